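# Benchmark metrics: technical-replicate variance, case/control train/test
# consistency (ROC/AUC), covariate correlation, adjacent-CpG agreement.

#' Probe-level variance across technical replicates
#'
#' Within each replicate group the per-probe sample variance (n-1
#' denominator) is computed and then averaged across groups; the grand mean
#' across probes is the usual scalar summary of residual technical noise.
#'
#' @param beta probes x samples matrix.
#' @param replicate_groups factor/vector giving the replicate group of each
#'   column; singleton groups are dropped with a warning.
#' @return List with `per_probe` (mean within-group variance per probe),
#'   `mean` (grand mean across probes) and `n_groups`.
#' @export
replicate_variance <- function(beta, replicate_groups) {
  g <- as.factor(replicate_groups)
  if (length(g) != ncol(beta))
    stop_gmqn("replicate_groups length must match the number of samples",
              class = "gmqn_validation_error")
  sizes <- table(g)
  singles <- names(sizes)[sizes < 2]
  if (length(singles)) {
    warning(sprintf("dropping %d singleton replicate group(s)",
                    length(singles)))
  }
  keep <- setdiff(levels(g), singles)
  if (!length(keep))
    stop_gmqn("no replicate group has >= 2 samples",
              class = "gmqn_validation_error")
  vs <- sapply(keep, function(lv) row_vars(beta[, g == lv, drop = FALSE]))
  per_probe <- rowMeans(vs, na.rm = TRUE)
  list(per_probe = per_probe, mean = mean(per_probe, na.rm = TRUE),
       n_groups = length(keep))
}

# vectorized Welch two-sample t-test over matrix rows
welch_rows <- function(x, g) {
  g <- as.factor(g)
  if (nlevels(g) != 2L)
    stop_gmqn("exactly two groups required", class = "gmqn_validation_error")
  a <- x[, g == levels(g)[1], drop = FALSE]
  b <- x[, g == levels(g)[2], drop = FALSE]
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- row_vars(a); vb <- row_vars(b)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  data.frame(estimate = ma - mb, statistic = t, df = df, p.value = p)
}

# rank-based (Mann-Whitney) AUC of scores against binary labels
auc_scores <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Train/test consistency of differential-methylation calls
#'
#' Samples are split into training and test sets (default 2:1, stratified by
#' group, or an explicit `train` index which allows the split to follow
#' batches).  A per-probe two-group Welch t-test is run in each split; the
#' training calls at a Benjamini-Hochberg threshold form the gold standard,
#' and the test-set p-value ranking is scored against it as an ROC.  The
#' Welch t-test is this package's documented stand-in for a generic
#' differential-methylation caller.
#'
#' @param beta probes x samples matrix.
#' @param labels two-level group label per sample.
#' @param split_ratio fraction of samples in the training set.
#' @param seed seed for the random split (ignored when `train` is given).
#' @param train optional logical/integer index of training samples.
#' @param alpha BH-adjusted significance threshold for the gold standard.
#' @param permute_test permute the test-split labels first (null control).
#' @return List with `auc`, `roc` (FPR/TPR points), `gold` (logical calls),
#'   `train_p`, `test_p`, `n_gold`.
#' @export
case_control_consistency <- function(beta, labels, split_ratio = 2 / 3,
                                     seed = 1L, train = NULL, alpha = 0.05,
                                     permute_test = FALSE) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 6L))
    stop_gmqn("need two groups with at least 6 samples each",
              class = "gmqn_validation_error")
  n <- ncol(beta)
  if (is.null(train)) {
    set.seed(seed)
    tr <- logical(n)
    for (lv in levels(labels)) {
      i <- which(labels == lv)
      tr[sample(i, round(length(i) * split_ratio))] <- TRUE
    }
  } else {
    tr <- logical(n); tr[train] <- TRUE
  }
  te_labels <- labels[!tr]
  if (permute_test) {
    set.seed(seed + 1L)
    te_labels <- sample(te_labels)
  }
  train_res <- welch_rows(beta[, tr, drop = FALSE], labels[tr])
  test_res <- welch_rows(beta[, !tr, drop = FALSE], te_labels)
  gold <- p.adjust(train_res$p.value, "BH") < alpha
  scores <- -log10(test_res$p.value)
  auc <- auc_scores(scores, gold)
  ord <- order(scores, decreasing = TRUE, na.last = NA)
  lab <- gold[ord]
  roc <- data.frame(fpr = c(0, cumsum(!lab) / max(sum(!lab, na.rm = TRUE), 1)),
                    tpr = c(0, cumsum(lab) / max(sum(lab, na.rm = TRUE), 1)))
  list(auc = auc, roc = roc, gold = gold, train_p = train_res$p.value,
       test_p = test_res$p.value, n_gold = sum(gold, na.rm = TRUE))
}

#' Per-probe Pearson correlation with a continuous covariate
#'
#' @param beta probes x samples matrix.
#' @param covariate numeric covariate per sample (e.g. age).
#' @param thresholds absolute-correlation thresholds to count.
#' @return List with `r` (per-probe Pearson r, `NA` for zero-variance
#'   probes, which are excluded from counts) and `counts` (probes with
#'   `|r| >=` each threshold).
#' @export
covariate_correlation <- function(beta, covariate,
                                  thresholds = c(0.5, 0.6, 0.7)) {
  if (length(covariate) != ncol(beta))
    stop_gmqn("covariate length must match the number of samples",
              class = "gmqn_validation_error")
  if (any(!is.finite(covariate)))
    stop_gmqn("covariate must be finite", class = "gmqn_validation_error")
  if (ncol(beta) < 10L)
    stop_gmqn("need at least 10 samples", class = "gmqn_validation_error")
  cc <- covariate - mean(covariate)
  m <- rowMeans(beta, na.rm = TRUE)
  x <- beta - m
  sx <- sqrt(rowSums(x^2, na.rm = TRUE))
  sy <- sqrt(sum(cc^2))
  r <- as.vector(x %*% cc) / (sx * sy)
  r[sx == 0] <- NA_real_
  counts <- vapply(thresholds, function(th) sum(abs(r) >= th, na.rm = TRUE),
                   numeric(1))
  names(counts) <- paste0("r", thresholds)
  list(r = r, counts = counts)
}

#' Select adjacent probe pairs from the annotation
#'
#' All probes on the same chromosome closer than `max_distance` (strict)
#' are paired greedily left-to-right, each probe used at most once.
#'
#' @param annotation probe annotation with chromosome/position.
#' @param max_distance pairs must satisfy `|pos_a - pos_b| < max_distance`.
#' @return data.frame with columns `probe_a`, `probe_b`.
#' @export
select_adjacent_pairs <- function(annotation, max_distance = 10L) {
  annotation <- validate_annotation(annotation)
  out <- list()
  for (chr in unique(annotation$chromosome)) {
    a <- annotation[annotation$chromosome == chr, ]
    a <- a[order(a$position), ]
    i <- 1L
    while (i < nrow(a)) {
      if (a$position[i + 1] - a$position[i] < max_distance) {
        out[[length(out) + 1L]] <- c(a$probe_id[i], a$probe_id[i + 1])
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(probe_a = character(0), probe_b = character(0),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(probe_a = m[, 1], probe_b = m[, 2], stringsAsFactors = FALSE)
}

#' Draw random control probe pairs
#'
#' @param annotation probe annotation.
#' @param n number of pairs.
#' @param seed seed for the draw.
#' @param exclude optional probe ids to exclude.
#' @return data.frame with columns `probe_a`, `probe_b` (distinct probes).
#' @export
select_random_pairs <- function(annotation, n, seed = 1L, exclude = NULL) {
  annotation <- validate_annotation(annotation)
  ids <- setdiff(annotation$probe_id, exclude)
  if (length(ids) < 2L)
    stop_gmqn("not enough probes to draw pairs",
              class = "gmqn_validation_error")
  set.seed(seed)
  a <- sample(ids, n, replace = TRUE)
  b <- sample(ids, n, replace = TRUE)
  fix <- which(a == b)
  while (length(fix)) {
    b[fix] <- sample(ids, length(fix), replace = TRUE)
    fix <- fix[a[fix] == b[fix]]
  }
  data.frame(probe_a = a, probe_b = b, stringsAsFactors = FALSE)
}

#' Mean absolute beta difference of adjacent vs random probe pairs
#'
#' Per sample, the mean `|beta_a - beta_b|` over the adjacent pairs and over
#' the random control pairs, and their ratio (adjacent / random); nearly
#' identical methylation of genomically adjacent CpGs makes a small ratio
#' the signature of low technical noise.
#'
#' @param beta probes x samples matrix.
#' @param pairs adjacent pairs (data.frame `probe_a`, `probe_b`).
#' @param random_pairs control pairs in the same format.
#' @return List with `per_sample` (data.frame: adjacent mean, random mean,
#'   ratio per sample), overall `adjacent_mean`, `random_mean`, `ratio`, and
#'   `n_skipped` pairs referencing missing probes.
#' @export
adjacent_pair_difference <- function(beta, pairs, random_pairs) {
  diff_set <- function(p) {
    ia <- match(p$probe_a, rownames(beta))
    ib <- match(p$probe_b, rownames(beta))
    keep <- !is.na(ia) & !is.na(ib)
    d <- abs(beta[ia[keep], , drop = FALSE] - beta[ib[keep], , drop = FALSE])
    list(mean = colMeans(d, na.rm = TRUE), skipped = sum(!keep))
  }
  adj <- diff_set(pairs); rnd <- diff_set(random_pairs)
  per_sample <- data.frame(sample_id = colnames(beta),
                           adjacent = adj$mean, random = rnd$mean,
                           ratio = adj$mean / rnd$mean,
                           stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       adjacent_mean = mean(adj$mean), random_mean = mean(rnd$mean),
       ratio = mean(adj$mean) / mean(rnd$mean),
       n_skipped = adj$skipped + rnd$skipped)
}
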