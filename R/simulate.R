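#' Simulation configuration for synthetic BeadChip signal data
#'
#' Defaults describe a desk-scale array with the distributional features the
#' normalization method targets: a bimodal beta distribution dominated by
#' extreme hypo/hyper methylation, per-probe log-normal total intensity
#' whose "dark probe" at extreme betas produces the two-Gaussian channel
#' structure of Infinium I probes, a monotone compression of Infinium II
#' betas toward 0.5, per-batch affine intensity distortions, and additive
#' background noise.
#'
#' @param n_type1_red,n_type1_green,n_type2 probe counts by design/channel.
#' @param n_samples number of samples.
#' @param beta_weights mixture weights of the hypo/mid/hyper beta states.
#' @param beta_shapes list of three `c(a, b)` beta shape pairs.
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of the
#'   per-probe total intensity (arbitrary units); drawn once per probe, so
#'   intensity is a stable probe property (affinity) across samples.
#' @param intensity_rep_sdlog sd (log scale) of the per-sample multiplicative
#'   jitter around each probe's total intensity.
#' @param background_sd sd of the additive Gaussian background noise.
#' @param bio_sd sd of the biological inter-individual beta variation added
#'   per probe and individual (shared across technical replicates and across
#'   the members of an adjacent pair).
#' @param type2_compression monotone compression of type II betas toward
#'   0.5: `beta' = 0.5 + (beta - 0.5) * (1 - compression)`.
#' @param batch_effects data.frame with one row per batch and columns
#'   `scale_red`, `shift_red`, `scale_green`, `shift_green`, `scale_type2`,
#'   `shift_type2` (all scales > 0); `NULL` means one identity batch.
#' @param sample_batches integer batch id per sample (default all 1).
#' @param groups optional character/factor of case/control labels per sample.
#' @param diff_frac fraction of probes truly differential between groups.
#' @param diff_delta absolute beta shift at differential probes (sign
#'   alternates across probes).
#' @param covariate optional numeric covariate per sample (e.g. age).
#' @param n_covariate_probes number of probes whose beta is linearly linked
#'   to the covariate.
#' @param covariate_r target per-probe Pearson correlation with the
#'   covariate (before intensity noise and batch distortion; biological
#'   variation is counted into the residual so the target is exact).
#' @param covariate_mu_range range of baseline beta levels for
#'   covariate-linked probes.
#' @param adjacent_pairs number of probe pairs constrained to share one true
#'   beta and placed < 10 bp apart.
#' @param seed integer seed; fully determines the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_type1_red = 1200L, n_type1_green = 1200L,
                       n_type2 = 2400L, n_samples = 2L,
                       beta_weights = c(0.45, 0.15, 0.40),
                       beta_shapes = list(c(1.5, 12), c(5, 5), c(12, 1.5)),
                       intensity_meanlog = log(10000), intensity_sdlog = 0.2,
                       intensity_rep_sdlog = 0.05,
                       background_sd = 40,
                       bio_sd = 0.02,
                       type2_compression = 0.2,
                       batch_effects = NULL,
                       sample_batches = NULL,
                       groups = NULL, diff_frac = 0, diff_delta = 0.1,
                       covariate = NULL, n_covariate_probes = 0L,
                       covariate_r = 0.8,
                       covariate_mu_range = c(0.15, 0.85),
                       adjacent_pairs = 0L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$batch_effects))
    cfg$batch_effects <- data.frame(scale_red = 1, shift_red = 0,
                                    scale_green = 1, shift_green = 0,
                                    scale_type2 = 1, shift_type2 = 0)
  if (is.null(cfg$sample_batches))
    cfg$sample_batches <- rep(1L, cfg$n_samples)
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$beta_weights) - 1) > 1e-8)
    stop_gmqn("beta_weights must sum to 1", class = "gmqn_validation_error")
  sc <- unlist(cfg$batch_effects[grep("^scale_", names(cfg$batch_effects))])
  if (any(sc <= 0))
    stop_gmqn("batch scales must be positive", class = "gmqn_validation_error")
  if (length(cfg$sample_batches) != cfg$n_samples)
    stop_gmqn("sample_batches length must equal n_samples",
              class = "gmqn_validation_error")
  if (any(!cfg$sample_batches %in% seq_len(nrow(cfg$batch_effects))))
    stop_gmqn("sample_batches reference undefined batches",
              class = "gmqn_validation_error")
  if (!is.null(cfg$groups) && length(cfg$groups) != cfg$n_samples)
    stop_gmqn("groups length must equal n_samples",
              class = "gmqn_validation_error")
  if (!is.null(cfg$covariate) && length(cfg$covariate) != cfg$n_samples)
    stop_gmqn("covariate length must equal n_samples",
              class = "gmqn_validation_error")
  if (cfg$background_sd < 0)
    stop_gmqn("background_sd must be >= 0", class = "gmqn_validation_error")
  invisible(cfg)
}

# annotation table for a config; pair members are consecutive probes 5 bp
# apart, all other probes 1 kb apart
.sim_annotation <- function(cfg) {
  n <- cfg$n_type1_red + cfg$n_type1_green + cfg$n_type2
  design <- c(rep("I", cfg$n_type1_red + cfg$n_type1_green),
              rep("II", cfg$n_type2))
  channel <- c(rep("red", cfg$n_type1_red), rep("green", cfg$n_type1_green),
               rep("none", cfg$n_type2))
  ord <- sample.int(n)                 # interleave designs along the genome
  design <- design[ord]; channel <- channel[ord]
  probe_id <- sprintf("cg%07d", seq_len(n))
  pos <- cumsum(rep(1000L, n))
  npair <- min(cfg$adjacent_pairs, floor(n / 2))
  pairs <- NULL
  if (npair > 0) {
    a_idx <- seq(1L, by = 2L, length.out = npair)
    b_idx <- a_idx + 1L
    pos[b_idx] <- pos[a_idx] + 5L
    pairs <- data.frame(probe_a = probe_id[a_idx], probe_b = probe_id[b_idx],
                        stringsAsFactors = FALSE)
  }
  ann <- data.frame(probe_id = probe_id, design_type = design,
                    channel = channel, chromosome = "chr1", position = pos,
                    probe_cpg_count = sample(0:4, n, replace = TRUE,
                                             prob = c(.2, .3, .25, .15, .1)),
                    stringsAsFactors = FALSE)
  list(annotation = ann, pairs = pairs)
}

# probes x samples matrix of true betas incl. pair sharing, covariate links
# and group effects
.sim_true_beta <- function(cfg, ann, pairs) {
  n <- nrow(ann)
  comp <- sample.int(3, n, replace = TRUE, prob = cfg$beta_weights)
  base <- vapply(comp, function(k)
    rbeta(1, cfg$beta_shapes[[k]][1], cfg$beta_shapes[[k]][2]), numeric(1))
  if (!is.null(pairs)) {
    ib <- match(pairs$probe_b, ann$probe_id)
    ia <- match(pairs$probe_a, ann$probe_id)
    base[ib] <- base[ia]
  }
  beta <- matrix(base, n, cfg$n_samples,
                 dimnames = list(ann$probe_id, NULL))
  truth_probe <- data.frame(probe_id = ann$probe_id, base_beta = base,
                            is_diff = FALSE, diff_sign = 0,
                            is_covariate = FALSE, slope = 0,
                            stringsAsFactors = FALSE)
  reserved <- if (!is.null(pairs))
    match(c(pairs$probe_a, pairs$probe_b), ann$probe_id) else integer(0)
  free <- setdiff(seq_len(n), reserved)

  if (cfg$n_covariate_probes > 0 && !is.null(cfg$covariate)) {
    ic <- free[seq_len(min(cfg$n_covariate_probes, length(free)))]
    free <- setdiff(free, ic)
    cv <- cfg$covariate
    cs <- (cv - mean(cv)) / sd(cv)
    for (i in ic) {
      mu <- runif(1, cfg$covariate_mu_range[1], cfg$covariate_mu_range[2])
      # covariate-driven beta sd, shrunk near the boundaries of [0,1] so the
      # linear model is not clipped; residual sd set so the total residual
      # (including the biological noise added below) hits the target r
      amp <- min(0.08, (mu - 0.05) / 2, (0.95 - mu) / 2)
      sig_tot <- amp * sqrt(1 / cfg$covariate_r^2 - 1)
      sig_e <- sqrt(max(sig_tot^2 - cfg$bio_sd^2, 0))
      beta[i, ] <- clamp(mu + amp * cs + rnorm(cfg$n_samples, 0, sig_e),
                         0.02, 0.98)
      truth_probe$is_covariate[i] <- TRUE
      truth_probe$slope[i] <- amp / sd(cv)
    }
  }

  if (!is.null(cfg$groups) && cfg$diff_frac > 0) {
    ndiff <- max(1L, round(cfg$diff_frac * n))
    id <- free[seq_len(min(ndiff, length(free)))]
    case <- cfg$groups == sort(unique(as.character(cfg$groups)))[1]
    sgn <- rep(c(1, -1), length.out = length(id))
    for (j in seq_along(id)) {
      i <- id[j]
      beta[i, case] <- clamp(beta[i, case] + sgn[j] * cfg$diff_delta,
                             0.01, 0.99)
      truth_probe$is_diff[i] <- TRUE
      truth_probe$diff_sign[i] <- sgn[j]
    }
  }

  if (cfg$bio_sd > 0) {
    E <- matrix(rnorm(n * cfg$n_samples, 0, cfg$bio_sd), n, cfg$n_samples)
    if (!is.null(pairs)) {
      ia <- match(pairs$probe_a, ann$probe_id)
      ib <- match(pairs$probe_b, ann$probe_id)
      E[ib, ] <- E[ia, ]               # adjacent pairs stay truly equal
    }
    beta <- clamp(beta + E, 0.005, 0.995)
  }
  list(beta = beta, truth_probe = truth_probe)
}

# turn a true-beta matrix into noisy, batch-distorted intensities
.sim_intensities <- function(cfg, ann, beta) {
  n <- nrow(beta); ns <- ncol(beta)
  sample_id <- sprintf("s%03d", seq_len(ns))
  M <- matrix(0, n, ns, dimnames = list(ann$probe_id, sample_id))
  U <- M
  is2 <- ann$design_type == "II"
  total_base <- rlnorm(n, cfg$intensity_meanlog, cfg$intensity_sdlog)
  for (s in seq_len(ns)) {
    b <- beta[, s]
    b[is2] <- 0.5 + (b[is2] - 0.5) * (1 - cfg$type2_compression)
    total <- total_base *
      exp(rnorm(n, 0, cfg$intensity_rep_sdlog))
    m <- b * total; u <- (1 - b) * total
    if (cfg$background_sd > 0) {
      m <- m + rnorm(n, 0, cfg$background_sd)
      u <- u + rnorm(n, 0, cfg$background_sd)
    }
    m <- pmax(m, 0); u <- pmax(u, 0)
    be <- cfg$batch_effects[cfg$sample_batches[s], ]
    for (ch in c("red", "green")) {
      i <- ann$design_type == "I" & ann$channel == ch
      m[i] <- be[[paste0("scale_", ch)]] * m[i] + be[[paste0("shift_", ch)]]
      u[i] <- be[[paste0("scale_", ch)]] * u[i] + be[[paste0("shift_", ch)]]
    }
    m[is2] <- be$scale_type2 * m[is2] + be$shift_type2
    u[is2] <- be$scale_type2 * u[is2] + be$shift_type2
    M[, s] <- m; U[, s] <- u
  }
  meth_signals(M, U)
}

#' Simulate a synthetic BeadChip dataset with known ground truth
#'
#' @param cfg a [sim_config()].
#' @return List with `signals` ([meth_signals]), `annotation` (data.frame)
#'   and `truth`: `beta` (true probes x samples betas, before type II
#'   compression, noise and batch distortion), `probes` (per-probe roles),
#'   `samples` (batch/group/covariate per sample) and `pairs`.
#' @examples
#' d <- simulate_dataset(sim_config(n_samples = 2, seed = 7))
#' range(compute_beta(d$signals), na.rm = TRUE)
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  anp <- .sim_annotation(cfg)
  tb <- .sim_true_beta(cfg, anp$annotation, anp$pairs)
  signals <- .sim_intensities(cfg, anp$annotation, tb$beta)
  colnames(tb$beta) <- colnames(signals$M)
  samples <- data.frame(sample_id = colnames(signals$M),
                        batch = cfg$sample_batches,
                        group = if (is.null(cfg$groups)) NA_character_
                                else as.character(cfg$groups),
                        covariate = if (is.null(cfg$covariate)) NA_real_
                                    else cfg$covariate,
                        stringsAsFactors = FALSE)
  list(signals = signals, annotation = anp$annotation,
       truth = list(beta = tb$beta, probes = tb$truth_probe,
                    samples = samples, pairs = anp$pairs))
}

#' Simulate technical replicates across batches
#'
#' Generates `n_samples` biological samples, each with its own true beta
#' profile, assayed `reps_per_sample` times; replicates are assigned
#' round-robin to `n_batches` batches with distinct affine distortions.
#' Covers both the few-samples-by-few-replicates and the
#' one-sample-by-many-replicates technical-replicate layouts.
#'
#' @param cfg a [sim_config()] (its `n_samples`, `sample_batches`, `groups`
#'   and `covariate` fields are ignored).
#' @param n_samples number of distinct biological samples.
#' @param reps_per_sample technical replicates per biological sample.
#' @param n_batches number of batches.
#' @param batch_effects optional batch-effect data.frame (one row per
#'   batch); by default distortions are drawn from the seed: scales in
#'   `[0.7, 1.4]`, shifts in `[0, 400]`, independently per channel and for
#'   type II probes.
#' @return As [simulate_dataset()], with `truth$samples$replicate_of`
#'   identifying the biological sample.
#' @export
simulate_replicates <- function(cfg, n_samples = 1L, reps_per_sample = 3L,
                                n_batches = 1L, batch_effects = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ns <- n_samples * reps_per_sample
  if (is.null(batch_effects)) {
    batch_effects <- data.frame(
      scale_red = runif(n_batches, 0.7, 1.4),
      shift_red = runif(n_batches, 0, 400),
      scale_green = runif(n_batches, 0.7, 1.4),
      shift_green = runif(n_batches, 0, 400),
      scale_type2 = runif(n_batches, 0.7, 1.4),
      shift_type2 = runif(n_batches, 0, 400))
  }
  batches <- rep_len(seq_len(n_batches), ns)
  cfg2 <- cfg
  cfg2$n_samples <- ns
  cfg2$sample_batches <- batches
  cfg2$batch_effects <- batch_effects
  # keep the elements present (assigning NULL would drop them and expose
  # $ partial matching, e.g. covariate -> covariate_r)
  cfg2["groups"] <- list(NULL); cfg2["covariate"] <- list(NULL)
  cfg2$n_covariate_probes <- 0L; cfg2$diff_frac <- 0
  .validate_sim_config(cfg2)
  anp <- .sim_annotation(cfg2)
  # fresh true beta per biological sample, copied across its replicates
  rep_of <- rep(seq_len(n_samples), each = reps_per_sample)
  beta <- matrix(NA_real_, nrow(anp$annotation), ns,
                 dimnames = list(anp$annotation$probe_id, NULL))
  probes_truth <- NULL
  for (b in seq_len(n_samples)) {
    cfgb <- cfg2; cfgb$n_samples <- 1L
    tb <- .sim_true_beta(cfgb, anp$annotation, anp$pairs)
    beta[, rep_of == b] <- tb$beta[, 1]
    if (b == 1L) probes_truth <- tb$truth_probe
  }
  signals <- .sim_intensities(cfg2, anp$annotation, beta)
  colnames(beta) <- colnames(signals$M)
  samples <- data.frame(sample_id = colnames(signals$M), batch = batches,
                        replicate_of = rep_of, stringsAsFactors = FALSE)
  list(signals = signals, annotation = anp$annotation,
       truth = list(beta = beta, probes = probes_truth, samples = samples,
                    pairs = anp$pairs))
}
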