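#' Fit a three-state beta mixture to beta values
#'
#' The BMIQ-style decomposition of a beta-value distribution into
#' unmethylated (U), hemimethylated (H) and methylated (M) states.
#' Initialization is deterministic: values are grouped at the hypo/hyper
#' cut-points 0.2 and 0.8 and each group seeds a component by method of
#' moments.  A group with fewer than 10 values falls back to fixed prior
#' shapes (U: Beta(2,18), H: Beta(5,5), M: Beta(18,2)) whose shapes are held
#' fixed during EM while the weight still adapts.  The M-step maximizes each
#' component's weighted beta log-likelihood from the current parameters
#' (generalized EM), so the log-likelihood is non-decreasing across
#' iterations.  For speed, inputs longer than `max_fit_n` are fitted on a
#' deterministic subsample (every k-th value of the sorted vector).
#'
#' @param x numeric vector of beta values; clamped to `[1e-6, 1 - 1e-6]`;
#'   at least 500 values required.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param max_fit_n subsample size cap for the fit.
#' @param init optional starting point: a `betamix3_fit` (or its
#'   `components` list) whose shapes and weights seed the EM instead of the
#'   threshold/method-of-moments initialization.  Used by [bmiq_adjust()] to
#'   anchor the type II fit in the same likelihood mode as the type I fit.
#' @return Object of class `betamix3_fit`: `components` is a list `U`, `H`,
#'   `M` each with `a`, `b`, `weight` (component means strictly increasing),
#'   plus `loglik`, `loglik_trace`, `n_iter`, `converged`, `fixed` (which
#'   components used prior shapes).
#' @export
fit_beta_mixture3 <- function(x, tol = 1e-5, max_iter = 500L,
                              max_fit_n = 50000L, init = NULL) {
  if (any(!is.finite(x)))
    stop_gmqn("beta values must be finite", class = "gmqn_validation_error")
  x <- clamp(x, 1e-6, 1 - 1e-6)
  if (length(x) < 500L)
    stop_gmqn("need at least 500 beta values (got %d)", length(x),
              class = "gmqn_degenerate_error")
  x <- sort(x)
  if (length(x) > max_fit_n) {
    idx <- unique(round(seq(1L, length(x), length.out = max_fit_n)))
    x <- x[idx]
  }
  n <- length(x)

  a <- b <- w <- numeric(3)
  fixed <- logical(3)
  if (!is.null(init)) {
    comps <- if (inherits(init, "betamix3_fit")) init$components
             else init
    for (k in 1:3) {
      cp <- comps[[k]]
      a[k] <- cp$a; b[k] <- cp$b; w[k] <- cp$weight
    }
    w <- pmax(w, 0.01); w <- w / sum(w)
  } else {
    prior_shapes <- list(c(2, 18), c(5, 5), c(18, 2))
    groups <- list(x[x < 0.2], x[x >= 0.2 & x <= 0.8], x[x > 0.8])
    for (k in 1:3) {
      g <- groups[[k]]
      if (length(g) < 10L) {
        a[k] <- prior_shapes[[k]][1]; b[k] <- prior_shapes[[k]][2]
        fixed[k] <- TRUE
      } else {
        mm <- .beta_mom(g)
        a[k] <- mm[1]; b[k] <- mm[2]
      }
      w[k] <- max(length(g) / n, 0.01)
    }
    w <- w / sum(w)
  }

  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ld <- sapply(1:3, function(k)
      log(w[k]) + dbeta(x, a[k], b[k], log = TRUE))
    lse <- logsumexp_rows(ld)
    ll <- sum(lse)
    trace[iter] <- ll
    r <- exp(ld - lse)
    w <- pmax(colMeans(r), 1e-8); w <- w / sum(w)
    for (k in 1:3) {
      if (fixed[k]) next
      upd <- .beta_wmle(x, r[, k], a[k], b[k])
      a[k] <- upd[1]; b[k] <- upd[2]
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }

  means <- a / (a + b)
  ord <- order(means)
  comps <- setNames(lapply(ord, function(k)
    list(a = a[k], b = b[k], weight = w[k])), c("U", "H", "M"))
  structure(list(components = comps, loglik = trace[iter],
                 loglik_trace = trace, n_iter = iter,
                 converged = converged, n = n,
                 fixed = setNames(fixed[ord], c("U", "H", "M"))),
            class = "betamix3_fit")
}

# method-of-moments beta shape estimates with guards
.beta_mom <- function(g) {
  m <- mean(g); v <- var(g)
  v <- min(max(v, 1e-6), m * (1 - m) * 0.999)
  f <- m * (1 - m) / v - 1
  c(max(m * f, 0.05), max((1 - m) * f, 0.05))
}

# weighted beta MLE step; never returns a worse objective than the start
.beta_wmle <- function(x, r, a0, b0) {
  sw <- sum(r)
  if (sw < 1e-8) return(c(a0, b0))
  slx <- sum(r * log(x)); sl1x <- sum(r * log1p(-x))
  nll <- function(par) {
    a <- exp(par[1]); bb <- exp(par[2])
    if (!is.finite(a) || !is.finite(bb) || a > 1e6 || bb > 1e6) return(1e12)
    -((a - 1) * slx + (bb - 1) * sl1x - sw * lbeta(a, bb))
  }
  p0 <- c(log(a0), log(b0))
  fit <- tryCatch(
    optim(p0, nll, method = "L-BFGS-B", lower = log(1e-3), upper = log(1e4),
          control = list(maxit = 25)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value > nll(p0)) return(c(a0, b0))
  exp(fit$par)
}

#' @export
print.betamix3_fit <- function(x, ...) {
  cat("three-state beta mixture fit (U/H/M)\n")
  for (nm in names(x$components)) {
    cp <- x$components[[nm]]
    cat(sprintf("  %s: a=%.3f b=%.3f weight=%.3f mean=%.3f\n",
                nm, cp$a, cp$b, cp$weight, cp$a / (cp$a + cp$b)))
  }
  cat(sprintf("  loglik=%.2f after %d iterations (converged=%s, n=%d)\n",
              x$loglik, x$n_iter, x$converged, x$n))
  invisible(x)
}

#' @export
coef.betamix3_fit <- function(object, ...) {
  unlist(object$components)
}
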