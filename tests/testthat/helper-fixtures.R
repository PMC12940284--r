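# Shared fixtures, memoized so expensive cohorts and pipeline runs are
# computed once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Study-scale synthetic cohort: 300 samples, 4 planted signatures (one
# diploid-like), 5% multiplicative noise.
study_cohort <- function() {
  memo("study_cohort", simulate_cohort(n_samples = 300, k = 4,
                                       noise_level = 0.05, seed = 101))
}

# Zero-noise variant of the same design, for stability assessment.
study_cohort_zero <- function() {
  memo("study_cohort_zero", simulate_cohort(n_samples = 300, k = 4,
                                            noise_level = 0, seed = 101))
}

# Full extraction + consensus on the study cohort (all four backends).
study_model <- function() {
  memo("study_model",
       suppressMessages(consensus_pipeline(study_cohort()$features, seed = 202)))
}

# Small cohort for fast module-level checks.
small_cohort <- function() {
  memo("small_cohort", simulate_cohort(n_samples = 120, k = 3,
                                       noise_level = 0.05, seed = 303))
}

# Lightweight backend configuration used where the full four-backend run
# would add nothing (bootstrap reruns, CLI plumbing checks).
light_config <- function(k_range = 2:6) {
  extraction_config(nmf = list(k_range = k_range, n_restarts = 10),
                    hdp = list(enabled = FALSE))
}

# Quick segment constructor for feature-module tests.
make_segments <- function(sample_id, cn, length_bp, chromosome = "1") {
  n <- max(length(sample_id), length(cn), length(length_bp))
  sample_id <- rep_len(sample_id, n)
  cn <- rep_len(cn, n)
  length_bp <- rep_len(length_bp, n)
  start <- rep(1, n)
  data.frame(sample_id = sample_id, chromosome = rep_len(chromosome, n),
             start_bp = start, end_bp = start + length_bp - 1,
             n_probes = NA_real_, seg_mean = NA_real_, total_cn = cn,
             stringsAsFactors = FALSE)
}

# Random L1-normalized non-negative vectors over the 28 categories.
random_profiles <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(n * 28, 0.3), n, 28)
    m / rowSums(m)
  })
}
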