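test_that("replicate variance handles exact cases and singleton groups", {
  beta <- matrix(c(0.2, 0.4, 0.3, 0.3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("a", "b")))
  rv <- replicate_variance(beta, c(1, 1))
  expect_equal(unname(rv$per_probe["p1"]), 0.02)  # var of {0.2, 0.4}
  expect_equal(unname(rv$per_probe["p2"]), 0)
  ident <- beta[, c(1, 1)]
  expect_equal(replicate_variance(ident, c(1, 1))$mean, 0)
  expect_warning(
    rv2 <- replicate_variance(cbind(beta, beta[, 1]), c(1, 1, 2)),
    "singleton")
  expect_equal(rv2$n_groups, 1L)
  expect_error(suppressWarnings(replicate_variance(beta, c(1, 2))),
               class = "gmqn_validation_error")
})

test_that("consistency AUC is 1 for perfectly concordant splits", {
  set.seed(81)
  n <- 24
  lab <- rep(c("case", "ctrl"), each = n / 2)
  beta <- matrix(runif(200 * n, 0.3, 0.4), 200, n,
                 dimnames = list(sprintf("p%03d", 1:200),
                                 sprintf("s%02d", 1:n)))
  # 20 probes with a strong, split-independent effect
  eff <- 1:20
  beta[eff, lab == "case"] <- beta[eff, lab == "case"] + 0.4
  cc <- case_control_consistency(beta, lab, seed = 1)
  expect_gt(cc$n_gold, 0)
  expect_equal(cc$auc, 1)
})

test_that("AUC agrees with brute-force sweep and an independent library", {
  set.seed(82)
  scores <- c(rnorm(60, 1), rnorm(90, 0))
  labels <- c(rep(TRUE, 60), rep(FALSE, 90))
  ours <- gmqn:::auc_scores(scores, labels)
  # brute force: probability a positive outscores a negative (ties half)
  pos <- scores[labels]; neg <- scores[!labels]
  brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(ours, brute, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("permuted test labels drive consistency toward chance", {
  set.seed(83)
  n <- 30
  lab <- rep(c("case", "ctrl"), each = n / 2)
  beta <- matrix(runif(400 * n, 0.3, 0.6), 400, n,
                 dimnames = list(sprintf("p%03d", 1:400),
                                 sprintf("s%02d", 1:n)))
  beta[1:40, lab == "case"] <- beta[1:40, lab == "case"] + 0.3
  aucs <- vapply(1:10, function(s)
    case_control_consistency(beta, lab, seed = s, permute_test = TRUE)$auc,
    numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("covariate correlation flags linear probes and excludes flat ones", {
  set.seed(84)
  age <- seq(20, 80, length.out = 30)
  beta <- matrix(runif(50 * 30), 50, 30,
                 dimnames = list(sprintf("p%02d", 1:50), NULL))
  beta[1, ] <- 0.2 + 0.005 * age          # exactly linear -> r = 1
  beta[2, ] <- 0.5                        # zero variance -> excluded
  cv <- covariate_correlation(beta, age)
  expect_equal(unname(cv$r[1]), 1, tolerance = 1e-12)
  expect_true(is.na(cv$r[2]))
  expect_gte(cv$counts[["r0.7"]], 1)
  # a null probe at n = 100 reaches |r| 0.3 with probability ~2e-3
  beta2 <- matrix(runif(200 * 100), 200, 100,
                  dimnames = list(sprintf("q%03d", 1:200), NULL))
  cv2 <- covariate_correlation(beta2, rnorm(100))
  expect_lt(max(abs(cv2$r)), 0.45)
  expect_lt(mean(abs(cv2$r) > 0.3), 0.02)
})

test_that("adjacent-pair selection respects the strict distance rule", {
  ann <- data.frame(probe_id = c("a", "b", "c", "d"),
                    design_type = "II", channel = "none",
                    chromosome = c("chr1", "chr1", "chr2", "chr2"),
                    position = c(100L, 105L, 100L, 110L),
                    probe_cpg_count = 1L, stringsAsFactors = FALSE)
  pairs <- select_adjacent_pairs(ann, max_distance = 10L)
  expect_equal(nrow(pairs), 1L)            # 100/105 pairs; 100/110 does not
  expect_setequal(unlist(pairs[1, ]), c("a", "b"))
})

test_that("greedy pairing matches brute-force enumeration on a fixture", {
  set.seed(85)
  pos <- sort(sample(1:2000, 20))
  ann <- data.frame(probe_id = sprintf("p%02d", 1:20), design_type = "II",
                    channel = "none", chromosome = "chr1", position = pos,
                    probe_cpg_count = 1L, stringsAsFactors = FALSE)
  got <- select_adjacent_pairs(ann, max_distance = 50L)
  # oracle: walk sorted positions, pair greedily, never reuse a probe
  used <- logical(20); oracle <- NULL
  i <- 1L
  while (i < 20L) {
    if (!used[i] && !used[i + 1] && pos[i + 1] - pos[i] < 50) {
      oracle <- rbind(oracle, c(ann$probe_id[i], ann$probe_id[i + 1]))
      used[c(i, i + 1)] <- TRUE; i <- i + 2L
    } else i <- i + 1L
  }
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(as.matrix(got), oracle, ignore_attr = TRUE)
})

test_that("adjacent-pair differences: exact zero, analytic random baseline", {
  d <- simulate_dataset(sim_small(n_samples = 2L, adjacent_pairs = 100L,
                                  seed = 86L))
  beta <- compute_beta(d$signals)
  self_pairs <- data.frame(probe_a = rownames(beta)[1:10],
                           probe_b = rownames(beta)[1:10])
  rnd <- select_random_pairs(d$annotation, 500L, seed = 2L)
  res <- adjacent_pair_difference(beta, self_pairs, rnd)
  expect_equal(res$adjacent_mean, 0)
  expect_lt(res$ratio, 1)

  # mean |b1 - b2| for independent draws from the bimodal beta mixture:
  # Monte-Carlo oracle straight from the generating mixture
  set.seed(87)
  draw <- function(n) {
    k <- sample.int(3, n, TRUE, prob = c(0.45, 0.15, 0.40))
    sh <- list(c(1.5, 12), c(5, 5), c(12, 1.5))
    vapply(k, function(i) rbeta(1, sh[[i]][1], sh[[i]][2]), numeric(1))
  }
  oracle <- mean(abs(draw(20000) - draw(20000)))
  tb <- d$truth$beta[, 1]
  ia <- match(rnd$probe_a, names(tb)); ib <- match(rnd$probe_b, names(tb))
  shared <- unique(c(d$truth$pairs$probe_a, d$truth$pairs$probe_b))
  keep <- !(rnd$probe_a %in% shared) & !(rnd$probe_b %in% shared)
  got <- mean(abs(tb[ia[keep]] - tb[ib[keep]]))
  expect_lt(abs(got - oracle) / oracle, 0.05)

  # pairs referencing unknown probes are skipped and counted
  bad <- rbind(rnd, data.frame(probe_a = "nope", probe_b = "nada"))
  res2 <- adjacent_pair_difference(beta, self_pairs, bad)
  expect_equal(res2$n_skipped, 1L)
})

test_that("metrics are invariant to probe and sample order", {
  d <- simulate_replicates(sim_small(seed = 88L), n_samples = 2L,
                           reps_per_sample = 6L, n_batches = 2L)
  beta <- compute_beta(d$signals)
  g <- d$truth$samples$replicate_of
  p <- sample(nrow(beta)); s <- sample(ncol(beta))
  rv1 <- replicate_variance(beta, g)
  rv2 <- replicate_variance(beta[p, s], g[s])
  expect_equal(rv1$mean, rv2$mean)
  age <- rnorm(ncol(beta), 50, 10)
  c1 <- covariate_correlation(beta, age)
  c2 <- covariate_correlation(beta[p, s], age[s])
  expect_equal(c1$counts, c2$counts)
  expect_equal(sort(c1$r), sort(c2$r))
})
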