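#' Fit a two-state Gaussian mixture to channel intensities
#'
#' The core fit behind the between-array step: intensities of a color
#' channel's Infinium I probes decompose into a low-mean "dark" state (the
#' unlit probe of extremely methylated or unmethylated CpGs) and a brighter,
#' more dispersed state.  The fit is deterministic: the input is sorted, the
#' two components are initialized from the halves below/above the median
#' (means at the 25th/75th percentiles, within-half standard deviations,
#' equal weights), and EM runs to a relative log-likelihood tolerance.
#' Internally the data are standardized so the fit is equivariant under
#' affine transforms `x -> a*x + b` of the input to near machine precision;
#' returned parameters are on the original intensity scale.
#'
#' @param x numeric vector of intensities (at least 50 finite values with
#'   positive variance).
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param channel optional channel label ("red"/"green") stored on the fit.
#' @return Object of class `gmm2_fit`: list with `state1`, `state2` (each
#'   `mean`, `sd`, `weight`; state1 has the smaller mean), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `n`, `channel`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 1000, 150), rnorm(500, 6000, 900))
#' fit_gmm2(x)
#' @export
fit_gmm2 <- function(x, tol = 1e-6, max_iter = 1000L, channel = NA_character_) {
  x <- x[is.finite(x)]
  if (length(x) < 50L)
    stop_gmqn("need at least 50 finite values to fit a 2-state mixture (got %d)",
              length(x), class = "gmqn_degenerate_error")
  if (var(x) == 0)
    stop_gmqn("degenerate data: all values equal %g", x[1],
              class = "gmqn_degenerate_error")
  x <- sort(x)                       # exact permutation invariance
  m0 <- mean(x); s0 <- sd(x)
  z <- (x - m0) / s0
  n <- length(z)
  rng <- z[n] - z[1]
  sd_floor <- 1e-8 * rng

  med <- median(z)
  lo <- z[z <= med]; hi <- z[z > med]
  mu <- c(quantile(z, 0.25, names = FALSE), quantile(z, 0.75, names = FALSE))
  sg <- c(max(sd(lo), 1e-3), max(sd(if (length(hi) > 1) hi else z), 1e-3))
  w <- c(0.5, 0.5)

  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ld <- cbind(log(w[1]) + dnorm(z, mu[1], sg[1], log = TRUE),
                log(w[2]) + dnorm(z, mu[2], sg[2], log = TRUE))
    lse <- logsumexp_rows(ld)
    ll <- sum(lse)
    trace[iter] <- ll
    r1 <- exp(ld[, 1] - lse)
    r2 <- 1 - r1
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8)
      stop_gmqn("component collapse: state %d lost all weight",
                if (n1 < n2) 1L else 2L, class = "gmqn_collapse_error")
    mu <- c(sum(r1 * z) / n1, sum(r2 * z) / n2)
    sg <- c(sqrt(sum(r1 * (z - mu[1])^2) / n1),
            sqrt(sum(r2 * (z - mu[2])^2) / n2))
    if (any(sg < sd_floor))
      stop_gmqn("component collapse: state %d sd below floor",
                which.min(sg), class = "gmqn_collapse_error")
    w <- c(n1 / n, n2 / n)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }

  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  comp <- function(i) list(mean = m0 + s0 * mu[i], sd = s0 * sg[i],
                           weight = w[i])
  structure(list(state1 = comp(1), state2 = comp(2),
                 loglik = trace[iter] - n * log(s0),
                 loglik_trace = trace - n * log(s0),
                 n_iter = iter, converged = converged, n = n,
                 channel = channel),
            class = "gmm2_fit")
}

#' @export
print.gmm2_fit <- function(x, ...) {
  cat("two-state Gaussian mixture fit",
      if (!is.na(x$channel)) sprintf("(%s channel)", x$channel) else "", "\n")
  cat(sprintf("  state1: mean=%.2f sd=%.2f weight=%.3f\n",
              x$state1$mean, x$state1$sd, x$state1$weight))
  cat(sprintf("  state2: mean=%.2f sd=%.2f weight=%.3f\n",
              x$state2$mean, x$state2$sd, x$state2$weight))
  cat(sprintf("  loglik=%.2f after %d iterations (converged=%s, n=%d)\n",
              x$loglik, x$n_iter, x$converged, x$n))
  invisible(x)
}

#' @export
coef.gmm2_fit <- function(object, ...) {
  c(mean1 = object$state1$mean, sd1 = object$state1$sd,
    weight1 = object$state1$weight,
    mean2 = object$state2$mean, sd2 = object$state2$sd,
    weight2 = object$state2$weight)
}

#' Posterior state membership under a fitted two-state mixture
#'
#' @param object a `gmm2_fit`.
#' @param newdata numeric vector of intensities.
#' @param ... unused.
#' @return data.frame with columns `state` (1 or 2, maximum posterior, ties
#'   to state 1) and `posterior` (posterior probability of the chosen state).
#' @export
predict.gmm2_fit <- function(object, newdata, ...) {
  assign_states(newdata, object)
}

#' Normal CDF for one mixture component
#'
#' @param x numeric vector.
#' @param comp list with `mean` and `sd` (sd > 0).
#' @param log.p return the log probability.
#' @param lower.tail direction of accumulation.
#' @return Cumulative probabilities.
#' @export
gaussian_cdf <- function(x, comp, log.p = FALSE, lower.tail = TRUE) {
  if (comp$sd <= 0)
    stop_gmqn("component sd must be positive", class = "gmqn_parameter_error")
  pnorm(x, comp$mean, comp$sd, log.p = log.p, lower.tail = lower.tail)
}

#' Normal quantile for one mixture component
#'
#' @param p probabilities, clamped to `[1e-10, 1 - 1e-10]`.
#' @param comp list with `mean` and `sd` (sd > 0).
#' @return Quantiles.
#' @export
gaussian_quantile <- function(p, comp) {
  if (comp$sd <= 0)
    stop_gmqn("component sd must be positive", class = "gmqn_parameter_error")
  qnorm(clamp(p, 1e-10, 1 - 1e-10), comp$mean, comp$sd)
}
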