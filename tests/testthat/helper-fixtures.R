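# shared fixtures, built lazily once per test run

.fixtures <- new.env(parent = emptyenv())

# the default-condition 65-patient cohort and its radiomic matrix
default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_cohort(cohort_config(seed = 101L))
    .fixtures$features <- extract_cohort_features(.fixtures$cohort)
  }
  list(cohort = .fixtures$cohort, features = .fixtures$features)
}

# a small cohort for structural checks
small_cohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulate_cohort(cohort_config(n_patients = 6, seed = 11L))
  .fixtures$small
}

# standard DSC acquisition constants used across map tests
dsc_pars <- function(nt = 50) {
  list(tr = 1.72, te = 0.035, n_timepoints = nt, baseline_window = 1:5)
}

# well-separated blobs for correlation-based clustering: each cluster gets
# its own random profile *shape* (Pearson similarity ignores per-patient
# offsets, so clusters must differ in direction, not mean level)
blob_matrix <- function(sizes, n_features = 10, scale = 6, sd = 1, seed = 5) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    center <- rnorm(n_features) * scale
    matrix(center, sizes[i], n_features, byrow = TRUE) +
      matrix(rnorm(sizes[i] * n_features, 0, sd), sizes[i])
  }))
  rownames(x) <- sprintf("P%02d", seq_len(nrow(x)))
  x
}
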