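#' Construct a set of per-probe signal intensities
#'
#' Container for the raw (or normalized) methylated/unmethylated intensities
#' of one or more arrays: two aligned probes-by-samples matrices.  Missing
#' measurements are `NA` and are propagated, never imputed, by every
#' downstream step.
#'
#' @param M,U numeric matrices (probes x samples) of methylated and
#'   unmethylated intensities, with identical dimnames; intensities must be
#'   non-negative where not `NA`.
#' @return An object of class `meth_signals`: a list with elements `M` and
#'   `U`.
#' @export
meth_signals <- function(M, U) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (!identical(dim(M), dim(U)))
    stop_gmqn("M and U dimensions differ", class = "gmqn_validation_error")
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop_gmqn("signal matrices need probe rownames and sample colnames",
              class = "gmqn_validation_error")
  if (!identical(dimnames(M), dimnames(U)))
    stop_gmqn("M and U dimnames differ", class = "gmqn_validation_error")
  if (anyDuplicated(rownames(M)))
    stop_gmqn("duplicated probe ids in signal matrix",
              class = "gmqn_validation_error")
  .check_nonneg(M, "Methylated"); .check_nonneg(U, "Unmethylated")
  structure(list(M = M, U = U), class = "meth_signals")
}

.check_nonneg <- function(x, what) {
  bad <- which(!is.na(x) & x < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_gmqn("negative %s intensity at probe %s, sample %s", what,
              rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]],
              class = "gmqn_validation_error")
  }
  invisible(NULL)
}

#' @export
print.meth_signals <- function(x, ...) {
  cat(sprintf("meth_signals: %d probes x %d samples\n", nrow(x$M), ncol(x$M)))
  cat(sprintf("  samples: %s\n",
              paste(head(colnames(x$M), 5), collapse = ", ")))
  na <- sum(is.na(x$M)) + sum(is.na(x$U))
  cat(sprintf("  missing cells: %d\n", na))
  invisible(x)
}

#' @export
dim.meth_signals <- function(x) dim(x$M)

.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a delimited methylated/unmethylated signal table
#'
#' Expects one probe-id column and, per sample, a
#' `<sample><suffix for methylated>` and `<sample><suffix for unmethylated>`
#' column pair (the minfi-style export used by GEO supplementary files).
#' Column matching is case-sensitive on the suffix pattern but insensitive to
#' column order; blank cells become missing values.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param probe_col name or index of the probe-id column (default first).
#' @param meth_pattern,unmeth_pattern regular expressions that identify the
#'   methylated / unmethylated column of a sample; the sample name is the
#'   column name with the pattern removed.
#' @param sep field separator; inferred from the file extension by default.
#' @return A [meth_signals] object.
#' @export
read_signal_table <- function(path, probe_col = 1L,
                              meth_pattern = "\\.Methylated$",
                              unmeth_pattern = "\\.Unmethylated$",
                              sep = .sep_for(path)) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop_gmqn("cannot parse signal table %s: %s",
                                  path, conditionMessage(e),
                                  class = "gmqn_format_error"))
  if (ncol(df) < 3L)
    stop_gmqn("signal table %s has too few columns", path,
              class = "gmqn_format_error")
  probes <- as.character(df[[probe_col]])
  cols <- names(df)
  mcols <- grep(meth_pattern, cols, value = TRUE)
  ucols <- grep(unmeth_pattern, cols, value = TRUE)
  msamp <- sub(meth_pattern, "", mcols)
  usamp <- sub(unmeth_pattern, "", ucols)
  if (!length(mcols))
    stop_gmqn("no methylated-signal columns match '%s'", meth_pattern,
              class = "gmqn_schema_error")
  orphan <- setdiff(msamp, usamp)
  if (length(orphan))
    stop_gmqn("sample '%s' has a Methylated but no Unmethylated column",
              orphan[1], class = "gmqn_schema_error")
  orphan_u <- setdiff(usamp, msamp)
  if (length(orphan_u))
    stop_gmqn("sample '%s' has an Unmethylated but no Methylated column",
              orphan_u[1], class = "gmqn_schema_error")
  M <- as.matrix(df[mcols[order(msamp)]]); colnames(M) <- sort(msamp)
  U <- as.matrix(df[ucols[order(usamp)]]); colnames(U) <- sort(usamp)
  storage.mode(M) <- "double"; storage.mode(U) <- "double"
  rownames(M) <- rownames(U) <- probes
  meth_signals(M, U)
}

#' Write a signal table
#'
#' Inverse of [read_signal_table()]; values round-trip to full double
#' precision as text.
#'
#' @param signals a [meth_signals] object.
#' @param path output path (`.csv` selects comma separation).
#' @export
write_signal_table <- function(signals, path) {
  samp <- colnames(signals$M)
  out <- data.frame(probe_id = rownames(signals$M), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in samp) {
    out[[paste0(s, ".Methylated")]] <- signals$M[, s]
    out[[paste0(s, ".Unmethylated")]] <- signals$U[, s]
  }
  write.table(out, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation manifest
#'
#' Required columns: `probe_id`, `design_type` (`I`/`II`), `channel`
#' (`red`/`green` for Infinium I, `none` for Infinium II), `chromosome`,
#' `position` (1-based), `probe_cpg_count` (CpGs in the probe body, used for
#' SWAN stratification).
#'
#' @param path path to a delimited text manifest.
#' @param sep field separator (inferred from extension by default).
#' @return A validated `data.frame`.
#' @export
read_annotation <- function(path, sep = .sep_for(path)) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               comment.char = ""),
    error = function(e) stop_gmqn("cannot parse annotation %s: %s", path,
                                  conditionMessage(e),
                                  class = "gmqn_format_error"))
  validate_annotation(df)
}

#' Validate a probe annotation table
#'
#' @param df a data.frame with the columns listed in [read_annotation()].
#' @return The validated data.frame (channel normalized to lower case,
#'   missing channel for Infinium II coerced to `"none"`).
#' @export
validate_annotation <- function(df) {
  need <- c("probe_id", "design_type", "channel", "chromosome", "position",
            "probe_cpg_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_gmqn("annotation lacks column(s): %s", paste(miss, collapse = ", "),
              class = "gmqn_schema_error")
  df$probe_id <- as.character(df$probe_id)
  if (anyDuplicated(df$probe_id))
    stop_gmqn("duplicated probe_id '%s' in annotation",
              df$probe_id[duplicated(df$probe_id)][1],
              class = "gmqn_validation_error")
  df$design_type <- toupper(as.character(df$design_type))
  if (!all(df$design_type %in% c("I", "II")))
    stop_gmqn("design_type must be 'I' or 'II'",
              class = "gmqn_validation_error")
  ch <- tolower(as.character(df$channel))
  ch[is.na(ch) | ch == ""] <- "none"
  df$channel <- ch
  bad1 <- df$design_type == "I" & !df$channel %in% c("red", "green")
  if (any(bad1))
    stop_gmqn("Infinium I probe '%s' must have channel red or green",
              df$probe_id[bad1][1], class = "gmqn_validation_error")
  bad2 <- df$design_type == "II" & df$channel != "none"
  if (any(bad2))
    stop_gmqn("Infinium II probe '%s' must have channel 'none'",
              df$probe_id[bad2][1], class = "gmqn_validation_error")
  df$position <- as.integer(df$position)
  if (any(!is.na(df$position) & df$position < 1L))
    stop_gmqn("positions are 1-based and must be >= 1",
              class = "gmqn_validation_error")
  df$probe_cpg_count <- as.integer(df$probe_cpg_count)
  if (any(!is.na(df$probe_cpg_count) & df$probe_cpg_count < 0L))
    stop_gmqn("probe_cpg_count must be >= 0",
              class = "gmqn_validation_error")
  df
}

#' Write a probe annotation manifest
#' @param annotation annotation data.frame.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Compute beta values from signal intensities
#'
#' beta = M / (M + U + offset).  The default offset is 0; an offset of 100 is
#' common elsewhere in the field and can be supplied.  Entries where the
#' denominator is zero (and any missing M or U) become `NA`.
#'
#' @param signals a [meth_signals] object (or a list with `M`/`U` matrices).
#' @param offset non-negative intensity offset added to the denominator.
#' @return Numeric matrix of beta values in `[0, 1]` (probes x samples).
#' @export
compute_beta <- function(signals, offset = 0) {
  if (!is.numeric(offset) || length(offset) != 1L || is.na(offset) ||
      offset < 0)
    stop_gmqn("offset must be a single non-negative number",
              class = "gmqn_parameter_error")
  den <- signals$M + signals$U + offset
  beta <- signals$M / den
  beta[!is.na(den) & den == 0] <- NA_real_
  beta
}

#' Write a beta-value matrix
#' @param beta probes x samples matrix.
#' @param path output path.
#' @export
write_beta <- function(beta, path) {
  out <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a beta-value matrix written by [write_beta()]
#' @param path input path.
#' @return probes x samples numeric matrix.
#' @export
read_beta <- function(path) {
  df <- read.table(path, header = TRUE, sep = .sep_for(path),
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1]); rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
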