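# shared fixtures, built once per test run and memoized

.fixture_env <- new.env(parent = emptyenv())

# small uncoupled cohort for structural tests: the study trial design shrunk in
# subjects/parcels/voxels so every stage runs in seconds
tiny_config <- function(seed = 1L, ...) {
  sim_config(n_subjects = 12L, n_parcels = 24L, voxels_per_parcel = 12L,
             trials_per_operation = 12L, rest_run_timepoints = 200L,
             seed = seed, ...)
}

tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- generate_cohort(tiny_config())
  }
  .fixture_env$tiny
}

# one subject at the full trial design (288 trials, 72 per operation) with
# reduced spatial size
design_subject <- function() {
  if (is.null(.fixture_env$design)) {
    cfg <- sim_config(n_subjects = 1L, n_parcels = 8L, voxels_per_parcel = 12L,
                      seed = 5L)
    .fixture_env$design <- list(cfg = cfg, subject = generate_cohort(cfg)[[1]])
  }
  .fixture_env$design
}

# brute-force Pearson correlation of columns, written independently of the
# package's fast path
oracle_cor <- function(x) {
  n <- ncol(x)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# random orthogonal 3x3 matrix (possibly a reflection)
random_orthogonal <- function(seed = 1L) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}
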