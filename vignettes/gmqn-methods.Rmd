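---
title: "Gaussian mixture quantile normalization: model, assumptions and design choices"
author: "gmqn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian mixture quantile normalization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmqn)
options(gmqn.verbose = FALSE)
```

## The problem

Most public HumanMethylation450/EPIC records are deposited as processed
methylated/unmethylated signal tables.  The control probes and out-of-band
signals that many normalization methods rely on are simply not there, yet the
data still carry dye bias, background differences, batch effects, and the
Infinium I/II probe-design bias.  This package normalizes such tables against
a *reference distribution*, so that a newly added sample can be calibrated to
the same scale as an existing corpus without reprocessing anything.

## The model

The methylation level of a CpG is summarized as
$$\beta = \frac{M}{M + U},$$
with $M$ and $U$ the methylated and unmethylated signal intensities.
`compute_beta()` uses offset 0 by default; an offset (commonly 100) can be
added to the denominator but is deliberately not the default.

Infinium I probes read both $M$ and $U$ in a single color channel.  Because
human methylation is strongly bimodal, one of the two probes of an extremely
methylated (or unmethylated) CpG emits almost no light; those dark signals
pile up in a low-intensity mode, and the remaining signals form a brighter,
more dispersed mode.  A channel's pooled Infinium I intensities are therefore
well approximated by a two-component Gaussian mixture
$$w_1\,\mathcal N(\mu_1,\sigma_1^2) + w_2\,\mathcal N(\mu_2,\sigma_2^2),
  \qquad \mu_1 < \mu_2 ,$$
and the fitted $(\mu_k, \sigma_k)$ behave as a fingerprint of the batch:
arrays processed together land on nearly the same parameters.

Normalization proceeds in three steps:

1. **Reference.** For each Infinium I probe, the median $M$ and median $U$
   across the reference cohort are taken; per color channel the medians are
   pooled into one vector and fitted with `fit_gmm2()`
   (`build_reference()`).  A reference can also be written down directly from
   eight Gaussian parameters (`make_reference_from_params()`) or loaded from
   JSON (`load_reference()`).
2. **Between-array.** For each sample and channel the same mixture is
   fitted, every intensity is assigned to the state with the larger
   posterior (ties to state 1), and each intensity is mapped through
   $$q = F^{-1}\!\left(F(x \mid \mu_k, \sigma_k)\ \middle|\
     \mu_k^{\mathrm{ref}}, \sigma_k^{\mathrm{ref}}\right),$$
   which for Gaussians equals the affine map
   $\mu_k^{\mathrm{ref}} + \sigma_k^{\mathrm{ref}}(x-\mu_k)/\sigma_k$
   (`gmqn_map()`, `normalize_type1()`).  Any distortion of the form
   $x \mapsto ax + b$ ($a>0$) of a channel is absorbed by the fit, so the
   normalized output is invariant to it — this is the precise sense in which
   dye bias and affine batch effects are removed.
3. **Within-array.** Infinium II probes, whose single-probe design
   compresses $\beta$ toward 0.5, are corrected against the normalized
   Infinium I probes: either on the $\beta$ scale with a BMIQ-style
   three-state beta-mixture quantile map (`bmiq_adjust()`), or on the
   intensity scale with a SWAN-style stratified subset-quantile map
   (`swan_adjust()`).  `gmqn_normalize(method =)` selects the arm
   (`"none"`, `"bmiq"`, `"swan"`).

## Estimation choices

**Two-state Gaussian EM** (`fit_gmm2()`).  The input is sorted (making the
fit exactly permutation invariant) and standardized internally; parameters
are mapped back afterwards.  Standardization makes the fit equivariant under
affine transforms of the data to near machine precision, which the
invariance property above requires — a raw-scale stopping rule can stop at a
different iteration for transformed data.  Initialization is deterministic:
component means at the 25th/75th percentiles, standard deviations from the
halves below/above the median, equal weights.  Convergence is declared when
the relative log-likelihood change falls below `tol` (default `1e-6`,
`max_iter = 1000`).  Constant input is an error, as is a component standard
deviation collapsing below $10^{-8}$ times the data range — collapse is
reported, never silently repaired.  There are no random restarts anywhere:
reproducible normalization of public data is the use case, so identical
inputs give bit-identical output.

**Three-state beta EM** (`fit_beta_mixture3()`).  Values are clamped to
$[10^{-6}, 1-10^{-6}]$ and grouped at the conventional hypo/hyper cut-points
0.2 and 0.8; each group seeds a component by method of moments.  A group
with fewer than 10 values falls back to fixed prior shapes (U: Beta(2,18),
H: Beta(5,5), M: Beta(18,2)) that stay fixed during EM while the weight
adapts.  The M-step maximizes each component's weighted log-likelihood with
L-BFGS-B started at the current parameters and keeps the old value if the
step does not improve it — a generalized EM, so the log-likelihood is
non-decreasing at every iteration (both fitters expose `loglik_trace` so
this is testable).  Inputs longer than 50,000 are fitted on a deterministic
subsample (every $k$-th value of the sorted vector) and the transform is
applied to all values.

**BMIQ details.**  The three-state likelihood on array-shaped data is
multimodal: the hemimethylated component can fit either a tight middle bump
or a broad background, and two same-distribution samples can land in
different modes, which would make the type I → type II map unstable.
`bmiq_adjust()` therefore fits type I freely, then refits type II *anchored*
at the type I solution with at most 25 EM iterations — enough to adapt to
the type II compression, not enough to hop modes.  U-state probes are mapped
by $\beta' = F^{-1}_{U_1}(F_{U_2}(\beta))$ (M symmetric), H-state probes by
the affine stretch sending the type II U/H and H/M posterior-equality
boundaries onto the type I boundaries, and a final monotone repair (a
cumulative maximum over the map evaluated on the sorted unique values)
removes any seam inversion between the pieces, so the composite map is
monotone on $[0,1]$ by construction.  A failed fit returns the input with a
warning — between-array output is already usable, so within-array correction
never corrupts data.

**SWAN details.**  Probes are stratified by the CpG count in the probe body,
capped at 3+ (strata `0,1,2,3+`), matching the subset design that keeps
strata populated on small arrays.  Within a stratum, each type II intensity
is replaced by the type I empirical quantile (linear interpolation between
order statistics, rank positions $(r-1)/(n-1)$) at its own within-stratum
rank; a stratum without type I probes falls back to the all-probes type I
quantile map with a warning.  Unlike the published SWAN, the type I probes
are a fixed anchor and never move.  Ranks are never inverted; ties can only
arise where the type I order statistics themselves tie (e.g. at the zero
floor).

**Numeric details.**  The CDF/quantile pair in `gmqn_map()` is evaluated on
the log scale of the nearer tail, so it agrees with the affine closed form
to ~$10^{-13}$ over any realistic range; the cumulative probability is
clamped to $[10^{-10}, 1-10^{-10}]$.  Mapped intensities are floored at 1.0
so that $\beta$ stays defined; hard state assignment can leave a small
discontinuity at the posterior boundary, which is accepted in exchange for
an exactly testable closed form.  Probes missing either signal propagate
`NA` through every stage — nothing is imputed.  Probes absent from the
annotation pass through unchanged with a logged warning.

## The synthetic-data generator

`simulate_dataset()` emulates the distributional features the method feeds
on, with full ground truth:

* true $\beta$ from a three-component beta mixture, weights
  `(0.45, 0.15, 0.40)` and shapes Beta(1.5,12) / Beta(5,5) / Beta(12,1.5) —
  the hypo/hyper-dominated bimodal shape of human methylomes;
* per-probe total intensity $T \sim \log\mathcal N(\log 10^4, 0.2)$, drawn
  once per probe: brightness is a stable probe property (affinity), with a
  5% log-normal per-sample jitter.  Intensities are $M = \beta T$,
  $U = (1-\beta)T$ — the dark-probe mechanism that produces the two-Gaussian
  channel structure — plus additive $\mathcal N(0, 40)$ background noise
  floored at zero (so the technical $\beta$ noise is
  $\approx 40\sqrt{(1-\beta)^2+\beta^2}/T$, sd $\approx 0.004$);
* biological inter-individual variation of $\beta$ (sd `bio_sd`, default
  0.02; shared across technical replicates and across the two members of an
  adjacent pair).  Without it every null probe is identical across samples,
  which is degenerate: group tests then resolve arbitrarily small coherent
  artifacts, and any batch–covariate correlation maps onto null probes with
  $|r| \approx 1$;
* Infinium II design bias as a linear compression toward 0.5
  (`type2_compression`, default 0.2);
* batch effects as per-batch affine distortions $x \mapsto ax+b$, separate
  for the red channel, the green channel and the type II probes — exactly
  the distortion class the between-array step provably removes.  Only the
  shift term moves $\beta$ for type I probes (a common scale cancels in the
  ratio), through $b(1-2\beta)/(aT+2b)$, so realistic levels of batch
  distortion act most strongly on extreme-$\beta$ probes and on type II
  probes;
* optional covariate-linked probes (exact target Pearson $r$, baseline
  levels across `covariate_mu_range`), case/control effects ($\pm\Delta\beta$
  at a chosen fraction of probes) and adjacent probe pairs sharing one true
  $\beta$ placed < 10 bp apart.

`simulate_replicates()` arranges biological samples × technical replicates
across batches (the one-sample-many-replicates and
few-samples-few-replicates layouts).

What the generator does **not** model: probe-specific batch effects (real
batch effects are not exactly affine), out-of-band/control signals,
detection p-values, heteroscedastic or multiplicative noise, and the fact
that real Infinium II probes read $M$ and $U$ in different color channels
(here a single affine pair distorts both).  Passing tests on simulated data
therefore demonstrate the method's contracts — equivariance, monotonicity,
orderings — for the distortion class it targets, not performance on any
particular real cohort.

## The benchmark suite

Four metrics mirror the standard evaluation procedures for methylation
normalization, on matrices of any origin:

* `replicate_variance()` — probe-level variance within technical replicate
  groups, averaged, with the grand mean as the scalar summary;
* `case_control_consistency()` — 2:1 train/test split (or an explicit
  split), per-probe Welch t-tests, Benjamini–Hochberg calls at 0.05 in the
  training split as the gold standard, test-split p-value ranking scored as
  an ROC/AUC.  The Welch t-test is a documented stand-in for whichever
  differential-methylation caller a user prefers; threshold and adjustment
  are arguments;
* `covariate_correlation()` — per-probe Pearson correlation against a
  continuous covariate, with counts above thresholds 0.5/0.6/0.7
  (zero-variance probes excluded);
* `adjacent_pair_difference()` with `select_adjacent_pairs()` (same
  chromosome, distance strictly below 10 bp, greedy left-to-right
  non-overlapping pairing) and `select_random_pairs()` — mean
  $|\Delta\beta|$ of adjacent vs random pairs and their ratio.

## Problem sizes and layouts used by the checks

The shipped tests and `scripts/acceptance.R` run everything on desk-scale
arrays — 1,200 type I probes per channel and 2,400 type II probes (600/600/
1,200 in the quick fixtures), cohorts of 8–120 samples — sizes chosen so the
whole suite exercises every code path in a few minutes while keeping each
mixture fit comfortably above its minimum-data requirements.  Three layouts
deserve explanation:

* *Replicate variance*: one sample × 56 technical replicates across three
  batches with strong, spread-out distortions (shifts up to 2,200 a.u.)
  applied to channels and type II probes.  The between-array step removes
  the type I part, the BMIQ step the type II part, so mean probe variance
  must order raw > between-array ≥ +BMIQ.
* *Case/control*: 60 samples, 1% truly differential probes at
  $\Delta\beta = 0.1$ against inter-individual sd 0.05 (a moderate EWAS
  effect, $d = 2$).  The training split is one clean batch; the test split
  spans two strongly distorted batches whose composition is imbalanced
  between groups (8:2 / 2:8) — the realistic situation where batch
  membership correlates with case status in whatever data were not used for
  training.  Affine distortions corrupt a two-group comparison only through
  *within-split* batch differences, which is why the test split spans more
  than one batch.  The permuted-label calibration (AUC 0.5) is estimated
  over 100 permutations because a single permutation's AUC is wide (the
  gold-standard probes share one case/control pattern, so their statistics
  move together under any one permutation).
* *Covariate regression*: 120 samples, age 20–80, nine batches assigned
  round-robin (independent of age) with strong background shifts (up to
  3,000 a.u. at $10^4$-scale intensities), mirroring the deliberate choice
  of high-batch-effect cohorts for this kind of benchmark; with affine
  distortions only, weaker batches would barely move mid-range $\beta$
  correlations.

## Known limitations

* The reference shipped by `build_reference()` is whatever cohort the user
  supplies; no default reference for real arrays is bundled.
* The method assumes the sample's channel mixtures are two-state; severely
  atypical methylomes (e.g. methyltransferase knockouts) violate the shared
  shape assumption that reference-based mapping relies on.
* Hard state assignment leaves a potential discontinuity at the posterior
  boundary; intensities are floored at 1.0 after mapping.
* IDAT parsing, GEO retrieval and probe-level batch models are out of
  scope; the interchange format is the delimited signal table.

## A minimal run

```{r example, eval = FALSE}
cohort <- simulate_dataset(sim_config(n_samples = 10, seed = 1))
ref <- build_reference(cohort$signals, cohort$annotation)

batch <- data.frame(scale_red = 1.4, shift_red = 300,
                    scale_green = 0.8, shift_green = 150,
                    scale_type2 = 1.2, shift_type2 = 400)
d <- simulate_dataset(sim_config(n_samples = 3, batch_effects = batch,
                                 sample_batches = rep(1, 3), seed = 2))
beta <- gmqn_normalize(d$signals, d$annotation, ref, method = "bmiq")
summary(as.vector(beta))
```
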