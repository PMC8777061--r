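# Internal helpers shared across modules.

# key=value logging to stderr; silenced via options(gmqn.verbose = FALSE)
log_kv <- function(event, ...) {
  if (!isTRUE(getOption("gmqn.verbose", TRUE))) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("event=", event)
  if (length(kv)) {
    msg <- paste(msg, paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  }
  message(msg)
  invisible(NULL)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# row-wise variance with NA removal, n-1 denominator; rows with < 2 values -> NA
row_vars <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}

# numerically stable log(sum(exp(...))) over columns of a matrix of log terms
logsumexp_rows <- function(lx) {
  mx <- do.call(pmax, as.data.frame(lx))
  mx + log(rowSums(exp(lx - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gmqn <- function(fmt, ..., class) {
  stop(structure(class = c(class, "gmqn_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
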