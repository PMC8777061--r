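# Within-array (probe-design bias) correction, anchored on the normalized
# Infinium I probes: adapted BMIQ on beta values, adapted SWAN on
# intensities.  Unlike their published forms, the type I probes are the
# fixed target and are never modified.

# posterior-equality boundary between two adjacent beta components; root of
# the weighted log-density difference between the component means, with a
# grid fallback when no sign change brackets a root
.beta_boundary <- function(c_lo, c_hi) {
  f <- function(b)
    (log(c_lo$weight) + dbeta(b, c_lo$a, c_lo$b, log = TRUE)) -
    (log(c_hi$weight) + dbeta(b, c_hi$a, c_hi$b, log = TRUE))
  m_lo <- c_lo$a / (c_lo$a + c_lo$b)
  m_hi <- c_hi$a / (c_hi$a + c_hi$b)
  lo <- min(m_lo, m_hi) + 1e-6; hi <- max(m_lo, m_hi) - 1e-6
  if (hi <= lo) return((m_lo + m_hi) / 2)
  r <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-9)$root,
                error = function(e) NULL)
  if (!is.null(r)) return(r)
  g <- seq(lo, hi, length.out = 512)
  s <- sign(f(g))
  i <- which(diff(s) != 0)
  if (length(i)) (g[i[1]] + g[i[1] + 1]) / 2 else (lo + hi) / 2
}

#' BMIQ-style correction of Infinium II beta values
#'
#' Fits a three-state beta mixture ([fit_beta_mixture3()]) separately to the
#' type I and type II beta values of each sample.  Type II probes are
#' assigned U/H/M by maximum posterior; U-state probes are quantile-mapped
#' from the type II U component onto the type I U component (M symmetric),
#' and H-state probes are moved by the affine stretch that sends the type II
#' U/H and H/M posterior boundaries onto the type I boundaries.  A final
#' monotone repair over the sorted unique beta values guarantees the
#' composite map is non-decreasing.  Type I probes are returned unchanged;
#' a failed mixture fit (or too few probes) falls back to returning the
#' input with a warning.
#'
#' @param beta probes x samples matrix (or a named vector) of beta values.
#' @param annotation probe annotation.
#' @param min_probes minimum type I and type II probes needed to fit.
#' @param ... passed to [fit_beta_mixture3()].
#' @return Adjusted beta matrix (same shape, `NA` preserved).
#' @export
bmiq_adjust <- function(beta, annotation, min_probes = 500L, ...) {
  vec_in <- is.null(dim(beta))
  if (vec_in) beta <- matrix(beta, ncol = 1,
                             dimnames = list(names(beta), "sample"))
  annotation <- validate_annotation(annotation)
  probes <- rownames(beta)
  t1 <- probes %in% annotation$probe_id[annotation$design_type == "I"]
  t2 <- probes %in% annotation$probe_id[annotation$design_type == "II"]
  out <- beta
  for (s in seq_len(ncol(beta))) {
    out[, s] <- .bmiq_one(beta[, s], t1, t2, min_probes,
                          sample_id = colnames(beta)[s], ...)
  }
  if (vec_in) out[, 1] else out
}

.bmiq_one <- function(b, t1, t2, min_probes, sample_id = "", ...) {
  i1 <- which(t1 & !is.na(b)); i2 <- which(t2 & !is.na(b))
  if (length(i1) < min_probes || length(i2) < min_probes) {
    warning(sprintf("sample %s: too few type I/II betas for BMIQ (%d/%d); returning input",
                    sample_id, length(i1), length(i2)))
    return(b)
  }
  fits <- tryCatch({
    f1 <- fit_beta_mixture3(b[i1], ...)
    # anchored refit: seed the type II fit at the type I solution and bound
    # the iterations.  The 3-beta likelihood is multimodal on array-shaped
    # data; a short EM from the anchor adapts to the type II shape without
    # hopping modes, keeping the quantile map between the fits stable
    f2 <- suppressWarnings(
      fit_beta_mixture3(b[i2], init = f1, max_iter = 25L, ...))
    list(f1 = f1, f2 = f2)
  }, error = function(e) NULL)
  if (is.null(fits)) {
    warning(sprintf("sample %s: beta-mixture fit failed; returning input",
                    sample_id))
    return(b)
  }
  c1 <- fits$f1$components; c2 <- fits$f2$components
  bU1 <- .beta_boundary(c1$U, c1$H); bM1 <- .beta_boundary(c1$H, c1$M)
  bU2 <- .beta_boundary(c2$U, c2$H); bM2 <- .beta_boundary(c2$H, c2$M)
  if (bM1 <= bU1 || bM2 <= bU2) {
    warning(sprintf("sample %s: degenerate state boundaries; returning input",
                    sample_id))
    return(b)
  }
  x <- clamp(b[i2], 1e-6, 1 - 1e-6)
  ux <- sort(unique(x))
  y <- numeric(length(ux))
  inU <- ux <= bU2
  inM <- ux > bM2
  inH <- !inU & !inM
  y[inU] <- qbeta(pbeta(ux[inU], c2$U$a, c2$U$b), c1$U$a, c1$U$b)
  y[inM] <- qbeta(pbeta(ux[inM], c2$M$a, c2$M$b), c1$M$a, c1$M$b)
  y[inH] <- bU1 + (ux[inH] - bU2) * (bM1 - bU1) / (bM2 - bU2)
  y <- clamp(y, 0, 1)
  y <- cummax(y)                     # monotone seam repair
  b[i2] <- y[match(x, ux)]
  b
}

#' SWAN-style correction of Infinium II intensities
#'
#' Adapted subset-quantile normalization with the (GMQN-normalized) type I
#' intensities as the fixed target.  Separately for the methylated and
#' unmethylated signal, probes are stratified by the CpG count in the probe
#' body (capped at 3+); within each stratum, every type II intensity is
#' replaced by the type I empirical quantile (linear interpolation between
#' order statistics) at that probe's within-stratum quantile.  A stratum
#' with no type I probes falls back to the all-probes type I quantile map
#' with a warning.  Type I probes are unchanged.
#'
#' @param signals a [meth_signals] object (normally the output of
#'   [normalize_type1()]).
#' @param annotation probe annotation with `probe_cpg_count`.
#' @param cap CpG-count cap defining the top stratum.
#' @return A [meth_signals] object with adjusted type II intensities.
#' @export
swan_adjust <- function(signals, annotation, cap = 3L) {
  annotation <- validate_annotation(annotation)
  probes <- rownames(signals$M)
  ann <- annotation[match(probes, annotation$probe_id), ]
  stratum <- pmin(ann$probe_cpg_count, cap)
  is1 <- !is.na(ann$design_type) & ann$design_type == "I"
  is2 <- !is.na(ann$design_type) & ann$design_type == "II"
  Mn <- signals$M; Un <- signals$U
  for (s in seq_len(ncol(Mn))) {
    Mn[, s] <- .swan_one(signals$M[, s], is1, is2, stratum)
    Un[, s] <- .swan_one(signals$U[, s], is1, is2, stratum)
  }
  meth_signals(Mn, Un)
}

.swan_one <- function(v, is1, is2, stratum) {
  all_t1 <- sort(v[is1 & !is.na(v)])
  for (st in unique(stratum[is2])) {
    if (is.na(st)) next
    i2 <- which(is2 & !is.na(v) & !is.na(stratum) & stratum == st)
    if (!length(i2)) next
    t1v <- v[is1 & !is.na(v) & !is.na(stratum) & stratum == st]
    if (!length(t1v)) {
      warning(sprintf("stratum %s has no type I probes; using all type I", st))
      t1v <- all_t1
    } else t1v <- sort(t1v)
    r <- rank(v[i2], ties.method = "average")
    p <- if (length(i2) > 1) (r - 1) / (length(i2) - 1) else 0.5
    v[i2] <- quantile(t1v, probs = p, type = 7, names = FALSE)
  }
  v
}

#' Full normalization pipeline
#'
#' Between-array normalization of Infinium I probes against the reference,
#' beta computation, then optional within-array Infinium II correction:
#' `method = "none"` (between-array only), `"bmiq"` (beta-mixture quantile
#' correction of type II betas) or `"swan"` (stratified subset-quantile
#' correction of type II intensities before beta computation).  These are
#' the GMQN, GMQN.BMIQ and GMQN.SWAN arms.
#'
#' @param signals a [meth_signals] object.
#' @param annotation probe annotation.
#' @param ref a `gmqn_reference`.
#' @param method one of "none", "bmiq", "swan".
#' @param offset beta offset (see [compute_beta()]).
#' @param floor intensity floor for mapped values.
#' @param workers number of parallel worker processes (per-sample
#'   parallelism; results are independent of the setting).
#' @param ... passed to [fit_gmm2()] via [normalize_type1()].
#' @return Beta matrix (probes x samples) with an attribute `fits` holding
#'   the per-sample channel mixture fits.
#' @export
gmqn_normalize <- function(signals, annotation, ref,
                           method = c("none", "bmiq", "swan"),
                           offset = 0, floor = 1, workers = 1L, ...) {
  method <- match.arg(method)
  annotation <- validate_annotation(annotation)
  probes <- rownames(signals$M)
  ann <- annotation
  run_one <- function(s) {
    res <- .normalize_type1_one(signals$M[, s], signals$U[, s], probes,
                                ann, ref, floor, tol = 1e-6,
                                max_iter = 1000L,
                                sample_id = colnames(signals$M)[s])
    if (method == "swan") {
      annm <- ann[match(probes, ann$probe_id), ]
      stratum <- pmin(annm$probe_cpg_count, 3L)
      is1 <- !is.na(annm$design_type) & annm$design_type == "I"
      is2 <- !is.na(annm$design_type) & annm$design_type == "II"
      res$M <- .swan_one(res$M, is1, is2, stratum)
      res$U <- .swan_one(res$U, is1, is2, stratum)
    }
    beta <- res$M / (res$M + res$U + offset)
    den0 <- !is.na(res$M) & !is.na(res$U) & (res$M + res$U + offset) == 0
    beta[den0] <- NA_real_
    if (method == "bmiq") {
      t1 <- probes %in% ann$probe_id[ann$design_type == "I"]
      t2 <- probes %in% ann$probe_id[ann$design_type == "II"]
      beta <- .bmiq_one(beta, t1, t2, min_probes = 500L,
                        sample_id = colnames(signals$M)[s])
    }
    list(beta = beta, fits = res$fits)
  }
  idx <- seq_len(ncol(signals$M))
  results <- if (workers > 1L) {
    parallel::mclapply(idx, run_one, mc.cores = workers)
  } else lapply(idx, run_one)
  err <- vapply(results, inherits, logical(1), "try-error")
  if (any(err))
    stop_gmqn("normalization failed for sample %s",
              colnames(signals$M)[which(err)[1]], class = "gmqn_sample_error")
  beta <- do.call(cbind, lapply(results, `[[`, "beta"))
  dimnames(beta) <- dimnames(signals$M)
  attr(beta, "fits") <- setNames(lapply(results, `[[`, "fits"),
                                 colnames(signals$M))
  beta
}
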