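# Shared fixtures, built in code and cached for the duration of the run.

options(gmqn.verbose = FALSE)

# desk-scale config; smaller probe counts than the package defaults keep the
# suite fast while leaving every stratum and mixture state well populated
sim_small <- function(...) {
  sim_config(n_type1_red = 600L, n_type1_green = 600L, n_type2 = 1200L, ...)
}

.fixtures <- new.env(parent = emptyenv())

# clean multi-sample cohort + reference fitted to it
fix_refdata <- function() {
  if (is.null(.fixtures$refdata)) {
    .fixtures$refdata <- simulate_dataset(
      sim_small(n_samples = 8L, seed = 20240100L))
  }
  .fixtures$refdata
}

fix_reference <- function() {
  if (is.null(.fixtures$ref)) {
    d <- fix_refdata()
    .fixtures$ref <- build_reference(d$signals, d$annotation)
  }
  .fixtures$ref
}

# minimal hand-built annotation: 2 type I (red/green) + 2 type II
tiny_annotation <- function() {
  data.frame(probe_id = c("cgA", "cgB", "cgC", "cgD"),
             design_type = c("I", "I", "II", "II"),
             channel = c("red", "green", "none", "none"),
             chromosome = "chr1",
             position = c(100L, 2100L, 4100L, 6100L),
             probe_cpg_count = c(1L, 2L, 1L, 3L),
             stringsAsFactors = FALSE)
}

expect_rel_equal <- function(x, y, rel_tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.eps)), rel_tol)
}

# the three benchmark arms: raw, between-array only, between-array + BMIQ
norm_arms <- function(d, ref) {
  norm <- normalize_type1(d$signals, d$annotation, ref)
  b_gmqn <- compute_beta(norm)
  b_bmiq <- bmiq_adjust(b_gmqn, d$annotation)
  list(raw = compute_beta(d$signals), gmqn = b_gmqn, bmiq = b_bmiq)
}
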