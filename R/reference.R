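REF_SCHEMA_VERSION <- "1.0"

#' Build a reference distribution from a cohort of samples
#'
#' For every Infinium I probe the median across samples of its methylated
#' and unmethylated intensity is taken; per color channel, the median M and
#' median U values of that channel's probes are pooled into one vector and a
#' two-state Gaussian mixture is fitted with [fit_gmm2()].  The two fitted
#' channel mixtures are the mapping target used by [normalize_type1()].
#'
#' @param signals a [meth_signals] object with one or more samples.
#' @param annotation probe annotation (see [read_annotation()]).
#' @param provenance free-text metadata stored with the model.
#' @param ... passed to [fit_gmm2()].
#' @return Object of class `gmqn_reference`: list with `red` and `green`
#'   `gmm2_fit`s, `n_samples`, `probe_counts`, `schema_version`,
#'   `provenance`.
#' @export
build_reference <- function(signals, annotation, provenance = "", ...) {
  annotation <- validate_annotation(annotation)
  probes <- rownames(signals$M)
  frac_na <- colMeans(is.na(signals$M) | is.na(signals$U))
  for (s in which(frac_na > 0.5))
    log_kv("reference_sample_sparse", sample = colnames(signals$M)[s],
           missing_fraction = round(frac_na[s], 3))
  fits <- list(); counts <- integer(0)
  for (ch in c("red", "green")) {
    ids <- annotation$probe_id[annotation$design_type == "I" &
                                 annotation$channel == ch]
    ids <- intersect(ids, probes)
    if (!length(ids))
      stop_gmqn("no Infinium I probes for the %s channel", ch,
                class = "gmqn_reference_error")
    medM <- apply(signals$M[ids, , drop = FALSE], 1, median, na.rm = TRUE)
    medU <- apply(signals$U[ids, , drop = FALSE], 1, median, na.rm = TRUE)
    pooled <- c(medM, medU)
    pooled <- pooled[is.finite(pooled)]
    fits[[ch]] <- fit_gmm2(pooled, channel = ch, ...)
    counts[ch] <- length(ids)
  }
  structure(list(red = fits$red, green = fits$green,
                 n_samples = ncol(signals$M), probe_counts = counts,
                 schema_version = REF_SCHEMA_VERSION,
                 provenance = provenance),
            class = "gmqn_reference")
}

#' Construct a reference model directly from Gaussian parameters
#'
#' @param red,green lists with `state1` and `state2`, each `mean`, `sd` and
#'   optionally `weight` (default 0.5); state1 must have the smaller mean.
#' @param provenance free-text metadata.
#' @return A `gmqn_reference` object with `converged = TRUE` fits.
#' @export
make_reference_from_params <- function(red, green, provenance = "manual") {
  mk <- function(p, ch) {
    for (s in c("state1", "state2")) {
      if (!all(c("mean", "sd") %in% names(p[[s]])))
        stop_gmqn("%s %s needs mean and sd", ch, s,
                  class = "gmqn_validation_error")
      if (p[[s]]$sd <= 0)
        stop_gmqn("%s %s sd must be positive", ch, s,
                  class = "gmqn_validation_error")
      p[[s]]$weight <- p[[s]]$weight %||% 0.5
    }
    if (p$state1$mean >= p$state2$mean)
      stop_gmqn("%s channel: state1 mean must be below state2 mean", ch,
                class = "gmqn_validation_error")
    structure(list(state1 = p$state1, state2 = p$state2,
                   loglik = NA_real_, loglik_trace = numeric(0),
                   n_iter = 0L, converged = TRUE, n = 0L, channel = ch),
              class = "gmm2_fit")
  }
  structure(list(red = mk(red, "red"), green = mk(green, "green"),
                 n_samples = 0L, probe_counts = integer(0),
                 schema_version = REF_SCHEMA_VERSION,
                 provenance = provenance),
            class = "gmqn_reference")
}

#' Save a reference model to JSON
#' @param ref a `gmqn_reference`.
#' @param path output path.
#' @export
save_reference <- function(ref, path) {
  ser_ch <- function(f) list(
    state1 = f$state1, state2 = f$state2, loglik = f$loglik,
    n_iter = f$n_iter, converged = f$converged, n = f$n, channel = f$channel)
  obj <- list(schema_version = ref$schema_version,
              red = ser_ch(ref$red), green = ser_ch(ref$green),
              n_samples = ref$n_samples,
              probe_counts = as.list(ref$probe_counts),
              provenance = ref$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a reference model from JSON
#' @param path path written by [save_reference()].
#' @return A `gmqn_reference` object.
#' @export
load_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$schema_version))
    stop_gmqn("reference file has no schema_version",
              class = "gmqn_schema_error")
  if (!identical(as.character(obj$schema_version), REF_SCHEMA_VERSION))
    stop_gmqn("reference schema version '%s' does not match supported '%s'",
              obj$schema_version, REF_SCHEMA_VERSION,
              class = "gmqn_schema_error")
  for (ch in c("red", "green"))
    if (is.null(obj[[ch]]))
      stop_gmqn("reference file lacks the %s channel mixture", ch,
                class = "gmqn_schema_error")
  de_ch <- function(o, ch) {
    for (s in c("state1", "state2"))
      if (is.null(o[[s]]) || is.null(o[[s]]$mean) || is.null(o[[s]]$sd))
        stop_gmqn("reference %s channel lacks %s parameters", ch, s,
                  class = "gmqn_schema_error")
    structure(list(state1 = o$state1, state2 = o$state2,
                   loglik = o$loglik %||% NA_real_,
                   loglik_trace = numeric(0),
                   n_iter = o$n_iter %||% 0L,
                   converged = isTRUE(o$converged),
                   n = o$n %||% 0L, channel = ch),
              class = "gmm2_fit")
  }
  red <- de_ch(obj$red, "red"); green <- de_ch(obj$green, "green")
  for (f in list(red, green))
    if (f$state1$mean >= f$state2$mean)
      stop_gmqn("%s channel: state1 mean must be below state2 mean",
                f$channel, class = "gmqn_validation_error")
  structure(list(red = red, green = green,
                 n_samples = obj$n_samples %||% 0L,
                 probe_counts = unlist(obj$probe_counts),
                 schema_version = as.character(obj$schema_version),
                 provenance = obj$provenance %||% ""),
            class = "gmqn_reference")
}

#' @export
print.gmqn_reference <- function(x, ...) {
  cat(sprintf("GMQN reference model (schema %s, %d samples)\n",
              x$schema_version, x$n_samples))
  for (ch in c("red", "green")) {
    f <- x[[ch]]
    cat(sprintf("  %s: state1 N(%.1f, %.1f) w=%.3f | state2 N(%.1f, %.1f) w=%.3f\n",
                ch, f$state1$mean, f$state1$sd, f$state1$weight,
                f$state2$mean, f$state2$sd, f$state2$weight))
  }
  if (nzchar(x$provenance %||% ""))
    cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}
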