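#' Hard state assignment under a fitted two-state mixture
#'
#' Each intensity is assigned to the mixture state with the larger posterior
#' probability; an exact tie goes to state 1 (the low-mean, "dark" state).
#'
#' @param values numeric vector of intensities.
#' @param mix a `gmm2_fit`.
#' @return data.frame with columns `state` (integer 1/2) and `posterior`
#'   (posterior probability of the chosen state, always >= 0.5).
#' @export
assign_states <- function(values, mix) {
  l1 <- log(mix$state1$weight) + dnorm(values, mix$state1$mean,
                                       mix$state1$sd, log = TRUE)
  l2 <- log(mix$state2$weight) + dnorm(values, mix$state2$mean,
                                       mix$state2$sd, log = TRUE)
  p1 <- 1 / (1 + exp(l2 - l1))
  state <- ifelse(p1 >= 0.5, 1L, 2L)
  data.frame(state = state, posterior = pmax(p1, 1 - p1))
}

#' Quantile-map an intensity from a source to a reference Gaussian state
#'
#' Computes `q = F^-1(F(x | source) | reference)` through the normal CDF and
#' quantile function, evaluated on the log scale of the nearer tail so the
#' numeric path agrees with the equivalent affine map
#' `ref$mean + ref$sd * (x - src$mean) / src$sd` to better than 1e-8 relative
#' over the working range.  The cumulative probability is clamped to
#' `[1e-10, 1 - 1e-10]` and mapped intensities are floored.
#'
#' @param values numeric vector.
#' @param src,ref lists with `mean` and `sd` (sd > 0): the fitted source
#'   state and the corresponding reference state.
#' @param floor minimum returned intensity (default 1).
#' @return Mapped intensities.
#' @export
gmqn_map <- function(values, src, ref, floor = 1) {
  if (is.null(src$sd) || !is.finite(src$sd) || src$sd <= 0)
    stop_gmqn("source component sd must be positive",
              class = "gmqn_parameter_error")
  if (is.null(ref$sd) || !is.finite(ref$sd) || ref$sd <= 0)
    stop_gmqn("reference component sd must be positive",
              class = "gmqn_parameter_error")
  out <- values
  ok <- !is.na(values)
  v <- values[ok]
  lower <- v <= src$mean
  lp <- numeric(length(v))
  lp[lower] <- pnorm(v[lower], src$mean, src$sd, log.p = TRUE,
                     lower.tail = TRUE)
  lp[!lower] <- pnorm(v[!lower], src$mean, src$sd, log.p = TRUE,
                      lower.tail = FALSE)
  lp <- pmax(lp, log(1e-10))          # rho clamp, on the accumulated tail
  q <- numeric(length(v))
  q[lower] <- qnorm(lp[lower], ref$mean, ref$sd, log.p = TRUE,
                    lower.tail = TRUE)
  q[!lower] <- qnorm(lp[!lower], ref$mean, ref$sd, log.p = TRUE,
                     lower.tail = FALSE)
  out[ok] <- pmax(q, floor)
  out
}

#' Between-array normalization of Infinium I probes
#'
#' The core between-array step: per sample and per color channel, the
#' methylated and unmethylated intensities of that channel's Infinium I
#' probes are pooled, a two-state Gaussian mixture is fitted with
#' [fit_gmm2()], every intensity is assigned to a state by maximum
#' posterior, and each intensity is quantile-mapped from its fitted state
#' onto the same-numbered state of the reference.  Infinium II probes (and
#' probes absent from the annotation, with a warning) pass through
#' untouched.  A probe with a missing M or U gets both outputs missing.
#'
#' @param signals a [meth_signals] object.
#' @param annotation probe annotation.
#' @param ref a `gmqn_reference`.
#' @param floor intensity floor applied to mapped values.
#' @param tol,max_iter passed to [fit_gmm2()].
#' @return A [meth_signals] object of normalized intensities with an
#'   attribute `fits`: per sample, the fitted red/green `gmm2_fit`s.
#' @export
normalize_type1 <- function(signals, annotation, ref, floor = 1,
                            tol = 1e-6, max_iter = 1000L) {
  annotation <- validate_annotation(annotation)
  probes <- rownames(signals$M)
  unknown <- setdiff(probes, annotation$probe_id)
  if (length(unknown))
    log_kv("probes_not_in_annotation", n = length(unknown))
  Mn <- signals$M; Un <- signals$U
  fits <- vector("list", ncol(Mn)); names(fits) <- colnames(Mn)
  for (s in seq_len(ncol(Mn))) {
    res <- .normalize_type1_one(signals$M[, s], signals$U[, s], probes,
                                annotation, ref, floor, tol, max_iter,
                                sample_id = colnames(Mn)[s])
    Mn[, s] <- res$M; Un[, s] <- res$U
    fits[[s]] <- res$fits
  }
  out <- meth_signals(Mn, Un)
  attr(out, "fits") <- fits
  out
}

.normalize_type1_one <- function(M, U, probes, annotation, ref, floor,
                                 tol, max_iter, sample_id = "") {
  fits <- list()
  for (ch in c("red", "green")) {
    ids <- annotation$probe_id[annotation$design_type == "I" &
                                 annotation$channel == ch]
    idx <- which(probes %in% ids)
    if (length(idx) < 50L)
      stop_gmqn("sample %s: fewer than 50 Infinium I probes in the %s channel",
                sample_id, ch, class = "gmqn_sample_error")
    vals <- c(M[idx], U[idx])
    obs <- which(is.finite(vals))
    fit <- tryCatch(
      fit_gmm2(vals[obs], tol = tol, max_iter = max_iter, channel = ch),
      error = function(e)
        stop_gmqn("sample %s: %s channel mixture fit failed: %s",
                  sample_id, ch, conditionMessage(e),
                  class = "gmqn_sample_error"))
    fits[[ch]] <- fit
    st <- assign_states(vals[obs], fit)$state
    mapped <- vals
    for (k in 1:2) {
      sel <- obs[st == k]
      if (!length(sel)) next
      mapped[sel] <- gmqn_map(vals[sel],
                              fit[[paste0("state", k)]],
                              ref[[ch]][[paste0("state", k)]],
                              floor = floor)
    }
    nm <- length(idx)
    M[idx] <- mapped[seq_len(nm)]
    U[idx] <- mapped[nm + seq_len(nm)]
    # missing propagation: a probe with either signal missing loses both
    half_na <- idx[xor(is.na(M[idx]), is.na(U[idx]))]
    M[half_na] <- NA_real_
    U[half_na] <- NA_real_
    log_kv("channel_fit", sample = sample_id, channel = ch,
           mean1 = round(fit$state1$mean, 2),
           mean2 = round(fit$state2$mean, 2),
           iterations = fit$n_iter)
  }
  list(M = M, U = U, fits = fits)
}
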