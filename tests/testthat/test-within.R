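test_that("BMIQ is near-identity when type II matches type I", {
  # package-default probe counts: the two mixture fits see enough probes
  # that fit noise stays inside the identity tolerance
  d <- simulate_dataset(sim_config(n_samples = 1L, type2_compression = 0,
                                   seed = 61L))
  beta <- compute_beta(d$signals)
  adj <- bmiq_adjust(beta, d$annotation)
  t2 <- rownames(beta) %in%
    d$annotation$probe_id[d$annotation$design_type == "II"]
  expect_lt(mean(abs(adj[t2, 1] - beta[t2, 1]), na.rm = TRUE), 0.01)
  # type I probes are the anchor and never move
  expect_identical(adj[!t2, 1], beta[!t2, 1])
})

test_that("BMIQ reverses a known monotone compression of type II betas", {
  d <- simulate_dataset(sim_small(n_samples = 1L, type2_compression = 0.25,
                                  seed = 62L))
  beta <- compute_beta(d$signals)
  adj <- bmiq_adjust(beta, d$annotation)
  t2 <- rownames(beta) %in%
    d$annotation$probe_id[d$annotation$design_type == "II"]
  before <- mean(abs(beta[t2, 1] - d$truth$beta[t2, 1]), na.rm = TRUE)
  after <- mean(abs(adj[t2, 1] - d$truth$beta[t2, 1]), na.rm = TRUE)
  expect_lt(after, 0.5 * before)
})

test_that("the BMIQ map is monotone on type II probes", {
  for (seed in c(63L, 64L)) {
    d <- simulate_dataset(sim_small(n_samples = 1L, seed = seed))
    beta <- compute_beta(d$signals)
    adj <- bmiq_adjust(beta, d$annotation)
    t2 <- rownames(beta) %in%
      d$annotation$probe_id[d$annotation$design_type == "II"]
    o <- order(beta[t2, 1])
    expect_true(all(diff(adj[t2, 1][o]) > -1e-9))
    expect_true(all(adj[, 1] >= 0 & adj[, 1] <= 1, na.rm = TRUE))
  }
})

test_that("BMIQ falls back to the input rather than corrupting data", {
  ann <- tiny_annotation()
  beta <- matrix(runif(4), 4, 1, dimnames = list(ann$probe_id, "s1"))
  expect_warning(out <- bmiq_adjust(beta, ann), "too few")
  expect_identical(out, beta)
})

test_that("SWAN matches type II to type I quantiles within strata", {
  d <- simulate_dataset(sim_small(n_samples = 1L, seed = 65L,
                                  type2_compression = 0.3))
  ann <- d$annotation
  adj <- swan_adjust(d$signals, ann)
  stratum <- pmin(ann$probe_cpg_count, 3L)
  t1 <- ann$design_type == "I"; t2 <- ann$design_type == "II"
  ids <- ann$probe_id
  for (st in unique(stratum[t2])) {
    v1 <- adj$M[ids[t1 & stratum == st], 1]
    v2 <- adj$M[ids[t2 & stratum == st], 1]
    q1 <- quantile(v1, 1:9 / 10, names = FALSE)
    q2 <- quantile(v2, 1:9 / 10, names = FALSE)
    expect_rel_equal(q2, q1, 0.02)
    # no rank inversions within the stratum (tied target order statistics
    # may merge neighbours, but never reorder them)
    raw2 <- d$signals$M[ids[t2 & stratum == st], 1]
    expect_true(all(diff(v2[order(raw2)]) >= 0))
  }
  # type I intensities never move
  expect_identical(adj$M[ids[t1], 1], d$signals$M[ids[t1], 1])
})

test_that("SWAN is identity when type II equals type I within every stratum", {
  # literal identity case: type II intensities are a permutation of the
  # type I intensities of the same stratum, so the quantile map must give
  # back the same values up to interpolation error
  d <- simulate_dataset(sim_small(n_samples = 1L, seed = 66L))
  ann <- d$annotation
  stratum <- pmin(ann$probe_cpg_count, 3L)
  t1 <- ann$design_type == "I"; t2 <- ann$design_type == "II"
  set.seed(660)
  for (st in unique(stratum)) {
    i1 <- which(t1 & stratum == st); i2 <- which(t2 & stratum == st)
    n <- min(length(i1), length(i2))
    i1 <- i1[1:n]; i2 <- i2[1:n]
    keep <- rep(TRUE, nrow(ann)); keep[setdiff(which(t1 | t2), c(i1, i2))] <- FALSE
    d$signals$M[ann$probe_id[i2], 1] <- sample(d$signals$M[ann$probe_id[i1], 1])
    d$signals$U[ann$probe_id[i2], 1] <- sample(d$signals$U[ann$probe_id[i1], 1])
  }
  # trim so each stratum has equal type I / type II counts
  eq_ids <- unlist(lapply(unique(stratum), function(st) {
    i1 <- ann$probe_id[t1 & stratum == st]; i2 <- ann$probe_id[t2 & stratum == st]
    n <- min(length(i1), length(i2)); c(i1[1:n], i2[1:n])
  }))
  sub <- meth_signals(d$signals$M[eq_ids, , drop = FALSE],
                      d$signals$U[eq_ids, , drop = FALSE])
  adj <- swan_adjust(sub, ann[ann$probe_id %in% eq_ids, ])
  i2_all <- intersect(eq_ids, ann$probe_id[t2])
  rel <- abs(adj$M[i2_all, 1] - sub$M[i2_all, 1]) / pmax(sub$M[i2_all, 1], 1)
  expect_lt(median(rel), 0.01)
  expect_lt(max(rel), 1e-8)   # equal counts: the map hits order statistics
})

test_that("pipeline arms compose as documented", {
  d <- simulate_dataset(sim_small(n_samples = 2L, seed = 67L))
  ref <- fix_reference()
  b_none <- gmqn_normalize(d$signals, d$annotation, ref, method = "none")
  direct <- compute_beta(normalize_type1(d$signals, d$annotation, ref))
  expect_identical(as.vector(b_none), as.vector(direct))
  for (m in c("bmiq", "swan")) {
    b <- gmqn_normalize(d$signals, d$annotation, ref, method = m)
    expect_true(all(b >= 0 & b <= 1, na.rm = TRUE))
  }
  # missing cells stay missing through every arm
  victim <- d$annotation$probe_id[d$annotation$design_type == "I"][1]
  d$signals$M[victim, 1] <- NA
  for (m in c("none", "bmiq", "swan")) {
    b <- gmqn_normalize(d$signals, d$annotation, ref, method = m)
    expect_true(is.na(b[victim, 1]))
    expect_false(is.na(b[victim, 2]))
  }
})
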