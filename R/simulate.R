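#' Default parcel-to-network labeling
#'
#' Assigns parcels to the four working-memory-operation networks (V, SM, DM,
#' FPC) in four contiguous, equal-as-possible blocks. Real analyses supply
#' their own labeling; the synthetic default only needs every parcel to carry
#' exactly one label.
#'
#' @param n_parcels number of cortical parcels (default 360).
#' @return factor of length `n_parcels` with levels `V, SM, DM, FPC`.
#' @export
default_network_labels <- function(n_parcels = 360L) {
  n_parcels <- .check_count(n_parcels, "n_parcels", min = 4L)
  idx <- cut(seq_len(n_parcels), breaks = 4L, labels = .networks)
  factor(idx, levels = .networks)
}

#' Default per-network operation geometry templates
#'
#' Each network is assigned a 4x4 target similarity matrix over the four
#' operations (maintain, replace, suppress, clear): the expected Pearson
#' correlation between noiseless operation prototypes in that network.
#' Defaults encode qualitatively distinct configurations: the visual network
#' represents all operations similarly (stimulus-driven), the sensorimotor
#' network groups maintain with replace, the default-mode network groups the
#' two removal operations (suppress, clear), and the frontoparietal-control
#' network keeps all four operations mutually distinct.
#'
#' @return named list of symmetric unit-diagonal 4x4 matrices, one per
#'   network, rows/columns named by operation.
#' @export
default_geometry_templates <- function() {
  mk <- function(fill) {
    m <- matrix(fill, 4L, 4L, dimnames = list(.operations, .operations))
    diag(m) <- 1
    m
  }
  v  <- mk(0.7)
  sm <- mk(0.2); sm["maintain", "replace"] <- sm["replace", "maintain"] <- 0.6
  dm <- mk(0.2); dm["suppress", "clear"] <- dm["clear", "suppress"] <- 0.6
  fpc <- mk(0.1)
  list(V = v, SM = sm, DM = dm, FPC = fpc)
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic cohort generator. Defaults
#' reproduce the study design: 48 subjects, 360 parcels in four networks,
#' 4 operations x 72 trials = 288 trials, two resting runs of 750 time points
#' at TR = 0.46 s, and three questionnaire scales coupled to a latent
#' thought-control-difficulty trait.
#'
#' @param n_subjects number of participants (default 48).
#' @param n_parcels number of cortical parcels (default 360).
#' @param network_labels factor mapping each parcel to one of V/SM/DM/FPC.
#' @param trials_per_operation trials per operation (default 72).
#' @param voxels_per_parcel voxels per parcel (default 50; minimum 8 so the
#'   prototype basis and noise channels fit).
#' @param tr_seconds repetition time in seconds (default 0.46).
#' @param rest_run_timepoints time points per resting run (default 750).
#' @param n_rest_runs number of resting runs (default 2).
#' @param geometry_templates per-network 4x4 operation-similarity targets;
#'   symmetric, unit diagonal, positive definite.
#' @param coupling list with elements `mixing` (named numeric, names of the
#'   form `"<network>.<operation>"`; blends that cell's parcel channel
#'   memberships toward uniform in proportion to the subject's latent
#'   difficulty, blurring the cell toward the whole-brain average profile),
#'   `variability` (same naming; scatters the cell's parcel memberships
#'   toward parcel-specific random channel mixtures, deforming the network's
#'   cloud in gradient space and increasing within-network heterogeneity),
#'   and `label_noise` (scalar; probability scale for trial-level lapses in
#'   which a trial's operation-specific engagement — the parcel-mean
#'   decodability channel — follows a different operation, degrading decoding
#'   accuracy while leaving multivoxel pattern geometry intact). All default
#'   to zero.
#' @param scale_noise_sd questionnaire noise sd on the latent (z) scale
#'   (default 0.5).
#' @param pattern_noise_sd total trial-pattern noise magnitude relative to the
#'   unit-norm prototypes (default 1, i.e. expected within-operation trial
#'   similarity about 0.5 before weighting).
#' @param noise_shares length-3 numeric summing to 1: variance shares of the
#'   network-shared, globally shared, and parcel-unique noise channels.
#' @param noise_rank dimensionality of the shared noise channels (default 3).
#' @param network_overlap admixture weight of the random cross-network channel
#'   memberships (default 0.3; 0 gives perfectly block-structured networks).
#' @param noise_signal_frac fraction of each shared channel's variance lying
#'   inside the operation-prototype subspace (default 0.6). This is the part
#'   of shared trial-to-trial variability that survives contrast weighting,
#'   as in real data where state fluctuations modulate discriminative
#'   dimensions too.
#' @param mean_signal_snr per-parcel signal-to-noise ratio of the
#'   operation-specific parcel-mean offsets that make parcel-mean features
#'   decodable (default 0.35; the offset sd is this multiple of the parcel-mean
#'   noise sd, so decodability is independent of voxel count). Pearson trial
#'   similarity is invariant to these per-trial constants.
#' @param trial_duration_tr,trial_gap_tr task-series trial length and
#'   inter-trial gap in TRs (defaults 6 and 4).
#' @param seed integer RNG seed; identical config + seed gives an identical
#'   cohort.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 48L,
                       n_parcels = 360L,
                       network_labels = default_network_labels(n_parcels),
                       trials_per_operation = 72L,
                       voxels_per_parcel = 50L,
                       tr_seconds = 0.46,
                       rest_run_timepoints = 750L,
                       n_rest_runs = 2L,
                       geometry_templates = default_geometry_templates(),
                       coupling = list(mixing = numeric(), variability = numeric(),
                                       label_noise = 0),
                       scale_noise_sd = 0.5,
                       pattern_noise_sd = 1,
                       noise_shares = c(network = 0.75, global = 0.05, unique = 0.2),
                       noise_rank = 3L,
                       network_overlap = 0.3,
                       noise_signal_frac = 0.6,
                       mean_signal_snr = 0.35,
                       trial_duration_tr = 6L,
                       trial_gap_tr = 4L,
                       seed = 1L) {
  cfg <- list(
    n_subjects = .check_count(n_subjects, "n_subjects"),
    n_parcels = .check_count(n_parcels, "n_parcels", min = 4L),
    network_labels = factor(network_labels, levels = .networks),
    n_operations = 4L,
    operations = .operations,
    trials_per_operation = .check_count(trials_per_operation, "trials_per_operation", min = 2L),
    voxels_per_parcel = .check_count(voxels_per_parcel, "voxels_per_parcel", min = 8L),
    tr_seconds = tr_seconds,
    rest_run_timepoints = .check_count(rest_run_timepoints, "rest_run_timepoints", min = 2L),
    n_rest_runs = .check_count(n_rest_runs, "n_rest_runs"),
    geometry_templates = geometry_templates,
    coupling = coupling,
    scale_noise_sd = scale_noise_sd,
    pattern_noise_sd = pattern_noise_sd,
    noise_shares = noise_shares,
    noise_rank = .check_count(noise_rank, "noise_rank", min = 1L),
    network_overlap = network_overlap,
    noise_signal_frac = noise_signal_frac,
    mean_signal_snr = mean_signal_snr,
    trial_duration_tr = .check_count(trial_duration_tr, "trial_duration_tr"),
    trial_gap_tr = .check_count(trial_gap_tr, "trial_gap_tr", min = 0L),
    seed = .check_count(seed, "seed", min = 0L)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  if (length(cfg$network_labels) != cfg$n_parcels || anyNA(cfg$network_labels)) {
    stop("network_labels must assign exactly one of V/SM/DM/FPC to every parcel")
  }
  if (!all(.networks %in% levels(cfg$network_labels))) {
    stop("network_labels must use levels V, SM, DM, FPC")
  }
  if (cfg$tr_seconds <= 0) stop("tr_seconds must be positive")
  if (cfg$network_overlap < 0 || cfg$network_overlap >= 1) {
    stop("network_overlap must be in [0, 1)")
  }
  if (cfg$noise_signal_frac < 0 || cfg$noise_signal_frac > 1) {
    stop("noise_signal_frac must be in [0, 1]")
  }
  for (nm in .networks) {
    g <- cfg$geometry_templates[[nm]]
    if (is.null(g) || !isTRUE(all.equal(g, t(g))) || any(abs(diag(g) - 1) > 1e-12)) {
      stop(sprintf("geometry template for %s must be symmetric with unit diagonal", nm))
    }
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) stop(sprintf("geometry template for %s must be positive definite", nm))
  }
  ns <- cfg$noise_shares
  if (length(ns) != 3L || any(ns < 0) || abs(sum(ns) - 1) > 1e-8) {
    stop("noise_shares must be 3 nonnegative values summing to 1")
  }
  for (fld in c("mixing", "variability")) {
    cp <- cfg$coupling[[fld]]
    if (length(cp)) {
      parts <- strsplit(names(cp), ".", fixed = TRUE)
      ok <- vapply(parts, function(p) length(p) == 2L && p[1] %in% .networks &&
                     p[2] %in% .operations, logical(1))
      if (!all(ok)) stop(sprintf("coupling$%s names must look like 'DM.suppress'", fld))
      if (any(cp < 0 | cp > 1)) stop(sprintf("coupling$%s must lie in [0, 1]", fld))
    }
  }
  invisible(cfg)
}

#' Configuration with the study's ground-truth couplings switched on
#'
#' Convenience wrapper around [sim_config()] that activates the three
#' couplings used in parameter-recovery experiments: default-mode suppress
#' pattern blurring (drives eccentricity down with difficulty),
#' frontoparietal suppress within-network variability (drives dispersion up),
#' and trial-label noise (drives decoding accuracy down).
#'
#' @param strength coupling strength in \[0, 1\] (default 0.8).
#' @param ... passed to [sim_config()].
#' @export
coupled_config <- function(strength = 0.8, ...) {
  sim_config(coupling = list(mixing = c(DM.suppress = strength),
                             variability = c(FPC.suppress = strength),
                             label_noise = strength),
             ...)
}

# per-(network, operation) channel sds for one subject, after applying the
# latent-difficulty couplings; returns list of 4x4 matrices net/glob/unique
#' @keywords internal
#' @noRd
.channel_scales <- function(cfg) {
  tot <- cfg$pattern_noise_sd^2
  list(shared = sqrt(tot * cfg$noise_shares[[1]]),
       glob = sqrt(tot * cfg$noise_shares[[2]]),
       unique = sqrt(tot * cfg$noise_shares[[3]]))
}

# per-parcel channel-membership weights: mostly the parcel's own network
# channel, with a random Dirichlet admixture of the other networks so that
# representational profiles overlap across networks (block-free structure, as
# cortical gradients require)
#' @keywords internal
#' @noRd
.base_memberships <- function(network_labels, overlap) {
  P <- length(network_labels)
  g <- matrix(stats::rexp(P * 4L), P, 4L)
  g <- g / rowSums(g)
  e <- diag(4L)[as.integer(network_labels), , drop = FALSE]
  w <- (1 - overlap) * e + overlap * g
  colnames(w) <- .networks
  w
}

# apply the latent-difficulty couplings for one operation: pattern mixing
# blends the targeted cell's membership weights toward uniform; within-network
# variability reallocates the cell's shared channel variance into parcel-unique
# noise, decorrelating its parcels from each other. Returns sqrt membership
# weights plus per-parcel shared/unique channel sds for that operation.
#' @keywords internal
#' @noRd
.coupled_cell_params <- function(w_base, network_labels, cfg, latent, op) {
  sc <- .channel_scales(cfg)
  P <- nrow(w_base)
  w <- w_base
  shared_var <- rep(sc$shared^2, P)
  unique_var <- rep(sc$unique^2, P)
  for (nm in names(cfg$coupling$mixing)) {
    p <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (p[2] != op) next
    m <- cfg$coupling$mixing[[nm]] * stats::pnorm(latent)
    rows <- network_labels == p[1]
    w[rows, ] <- (1 - m) * w[rows, , drop = FALSE] + m * 0.25
  }
  for (nm in names(cfg$coupling$variability)) {
    p <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (p[2] != op) next
    v <- cfg$coupling$variability[[nm]] * stats::pnorm(latent)
    rows <- which(network_labels == p[1])
    # parcel-wise scatter: each member parcel drifts toward its own random
    # channel mixture, deforming the network's cloud in gradient space
    xi <- matrix(stats::rexp(length(rows) * 4L), length(rows), 4L)
    xi <- xi / rowSums(xi)
    w[rows, ] <- (1 - v) * w[rows, , drop = FALSE] + v * xi
  }
  list(w_sqrt = sqrt(w), s_shared = sqrt(shared_var), s_unique = sqrt(unique_var))
}

# orthonormal basis with zero-mean columns (orthogonal to the constant vector),
# so prototype inner products equal their Pearson correlations exactly
#' @keywords internal
#' @noRd
.zero_mean_basis <- function(n, k) {
  g <- matrix(stats::rnorm(n * (k + 1L)), n, k + 1L)
  g[, 1L] <- 1
  q <- qr.Q(qr(g))[, -1L, drop = FALSE]
  q
}

# random near-isometric map from channel space into voxel space, with columns
# orthogonal to the constant vector and to the operation prototypes (so noise
# does not leak into parcel means or signal-noise cross terms), unit-scaled
#' @keywords internal
#' @noRd
.zero_mean_noise_map <- function(n, k, ortho_to = NULL) {
  a <- matrix(stats::rnorm(n * k), n, k)
  q <- cbind(rep(1 / sqrt(n), n), ortho_to)
  a <- a - q %*% crossprod(q, a)
  sweep(a, 2L, sqrt(colSums(a^2)), "/")
}

#' Generate trial-wise multivoxel patterns for one subject
#'
#' For every parcel, builds four unit-norm operation prototypes whose pairwise
#' Pearson correlations equal the parcel's network geometry template (via a
#' Cholesky factorization over a zero-mean orthonormal voxel basis), then adds
#' trial noise with three components: four network channels shared across
#' parcels and weighted by each parcel's channel membership (its own network
#' plus a Dirichlet admixture of the others, so representational profiles
#' overlap smoothly across networks), a globally shared channel, and
#' parcel-unique noise; plus an operation-specific parcel-mean offset.
#' Latent-difficulty couplings act on the membership weights of the targeted
#' (network, operation) cells — blending them toward uniform (pattern mixing:
#' the cell's parcels drift toward the whole-brain average profile) or
#' scattering them parcel-wise (within-network variability) — and label noise
#' makes some trials' engagement channel follow a different operation.
#'
#' Draws from the current RNG stream; [generate_cohort()] seeds it once.
#'
#' @param subject_params list with at least `latent_difficulty`; optionally
#'   `membership_base` (parcel x channel weights from the cohort level — the
#'   shared anatomy; freshly drawn when absent).
#' @param config a [sim_config()].
#' @return list with `patterns` (parcel x trial x voxel array),
#'   `trial_operations` (nominal labels, factor), `executed_operations`
#'   (labels after label noise), and `parcel_means` (parcel x operation
#'   offsets).
#' @export
generate_trial_patterns <- function(subject_params, config) {
  cfg <- config
  if (cfg$voxels_per_parcel < 2L) stop("voxels_per_parcel must be at least 2")
  d <- subject_params$latent_difficulty
  if (!is.finite(d)) stop("subject_params$latent_difficulty must be a finite number")
  P <- cfg$n_parcels; V <- cfg$voxels_per_parcel
  Tn <- cfg$trials_per_operation * cfg$n_operations
  k <- cfg$noise_rank
  ops <- factor(rep(.operations, each = cfg$trials_per_operation), levels = .operations)
  ops <- ops[sample.int(Tn)]                       # pseudo-random trial order

  # label noise: the trial's engagement (mean-offset) channel follows a
  # different operation with probability p(d); pattern geometry keeps the
  # labeled operation
  p_swap <- min(0.5, 0.35 * cfg$coupling$label_noise * stats::pnorm(d))
  executed <- ops
  if (p_swap > 0) {
    swap <- stats::runif(Tn) < p_swap
    if (any(swap)) {
      executed <- as.character(ops)
      executed[swap] <- vapply(executed[swap], function(o) {
        sample(setdiff(.operations, o), 1L)
      }, character(1))
      executed <- factor(executed, levels = .operations)
    }
  }
  op_idx <- as.integer(ops)
  mean_idx <- as.integer(executed)

  sc <- .channel_scales(cfg)
  k <- cfg$noise_rank
  # shared low-rank noise draws: one stream per network channel plus a global
  eta <- lapply(seq_len(5L), function(i) matrix(stats::rnorm(k * Tn, sd = 1 / sqrt(k)), k, Tn))
  # each channel's in-signal-subspace loadings, shared across parcels so the
  # corresponding similarity fluctuations are parcel-consistent and survive
  # contrast weighting
  gam <- cfg$noise_signal_frac
  l_eta <- lapply(seq_len(5L), function(c) {
    L <- matrix(stats::rnorm(4L * k), 4L, k)
    L <- L * sqrt(k) / sqrt(sum(L^2))
    L %*% eta[[c]]                      # 4 x Tn, shared across parcels
  })

  w_base <- subject_params$membership_base
  if (is.null(w_base)) w_base <- .base_memberships(cfg$network_labels, cfg$network_overlap)
  cell <- lapply(.operations, function(op) {
    .coupled_cell_params(w_base, cfg$network_labels, cfg, d, op)
  })
  names(cell) <- .operations

  # parcel-mean noise comes only from the full-rank unique channel (the shared
  # channels are zero-mean over voxels), with sd s_unique / V
  mean_noise_sd <- cfg$pattern_noise_sd * sqrt(cfg$noise_shares[[3]]) / V
  parcel_means <- matrix(stats::rnorm(P * 4L, sd = cfg$mean_signal_snr * mean_noise_sd),
                         P, 4L, dimnames = list(NULL, .operations))
  patterns <- array(NA_real_, dim = c(P, Tn, V))
  # per-trial channel scales for the current parcel
  wt <- matrix(NA_real_, 4L, Tn)
  s_uni_t <- numeric(Tn)
  for (p in seq_len(P)) {
    net <- as.character(cfg$network_labels[p])
    basis <- .zero_mean_basis(V, 4L)
    proto <- basis %*% chol(cfg$geometry_templates[[net]])
    x <- proto[, op_idx, drop = FALSE]
    noise_maps <- lapply(seq_len(5L), function(i) .zero_mean_noise_map(V, k, basis))
    chan <- lapply(seq_len(5L), function(c) {
      sqrt(gam) * (basis %*% l_eta[[c]]) + sqrt(1 - gam) * (noise_maps[[c]] %*% eta[[c]])
    })
    for (o in seq_len(4L)) {
      idx <- which(op_idx == o)
      cl <- cell[[o]]
      wt[, idx] <- cl$w_sqrt[p, ] * cl$s_shared[p]
      s_uni_t[idx] <- cl$s_unique[p]
    }
    for (c in seq_len(4L)) {
      x <- x + chan[[c]] * rep(wt[c, ], each = V)
    }
    x <- x + chan[[5L]] * sc$glob
    x <- x + matrix(stats::rnorm(V * Tn, sd = 1 / sqrt(V)), V, Tn) * rep(s_uni_t, each = V)
    x <- x + rep(parcel_means[p, mean_idx], each = V)
    patterns[p, , ] <- t(x)
  }
  list(patterns = patterns, trial_operations = ops,
       executed_operations = executed, parcel_means = parcel_means)
}

#' Generate resting-state runs for one subject
#'
#' Stationary multivariate series from a network factor model (one shared
#' factor per network plus a global factor), standardized per parcel within
#' each run. Resting dynamics are not coupled to the latent trait.
#'
#' @param subject_params list with `latent_difficulty` (unused; kept for a
#'   uniform generator signature).
#' @param config a [sim_config()].
#' @param b_network,b_global variance shares of the network and global factors
#'   (defaults 0.3 and 0.1).
#' @return list of `n_rest_runs` matrices, each time x parcel.
#' @export
generate_rest_timeseries <- function(subject_params, config, b_network = 0.3, b_global = 0.1) {
  cfg <- config
  P <- cfg$n_parcels; Tn <- cfg$rest_run_timepoints
  net_idx <- as.integer(cfg$network_labels)
  b_u <- 1 - b_network - b_global
  if (b_u < 0) stop("b_network + b_global must be <= 1")
  lapply(seq_len(cfg$n_rest_runs), function(run) {
    f_net <- matrix(stats::rnorm(Tn * 4L), Tn, 4L)
    f_glob <- stats::rnorm(Tn)
    y <- sqrt(b_network) * f_net[, net_idx, drop = FALSE] +
      sqrt(b_global) * matrix(f_glob, Tn, P) +
      sqrt(b_u) * matrix(stats::rnorm(Tn * P), Tn, P)
    z <- scale(y)
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    z
  })
}

#' Generate questionnaire totals from the latent trait
#'
#' Each scale is `loading x latent + noise` on the z scale, mapped into the
#' scale's published range (WBSI 15-75, PSWQ 16-80, RRS-brooding 5-20) with
#' midpoint centering and range/6 spread, then clipped to the range.
#'
#' @param latent_difficulty numeric vector of latent trait values.
#' @param config a [sim_config()].
#' @param loadings per-scale loadings (default 1 each).
#' @return data.frame with columns `WBSI`, `PSWQ`, `RRS_brooding`.
#' @export
generate_questionnaires <- function(latent_difficulty, config,
                                    loadings = c(WBSI = 1, PSWQ = 1, RRS_brooding = 1)) {
  ranges <- list(WBSI = c(15, 75), PSWQ = c(16, 80), RRS_brooding = c(5, 20))
  n <- length(latent_difficulty)
  out <- lapply(names(ranges), function(nm) {
    z <- loadings[[nm]] * latent_difficulty + stats::rnorm(n, sd = config$scale_noise_sd)
    r <- ranges[[nm]]
    raw <- mean(r) + diff(r) / 6 * z
    .clip(raw, r[1], r[2])
  })
  names(out) <- names(ranges)
  as.data.frame(out)
}

#' Generate a synthetic cohort
#'
#' Draws each subject's latent thought-control-difficulty trait from a
#' standard normal, then generates trial patterns, resting runs, a boxcar
#' task time series, and questionnaire totals. All randomness flows from a
#' single stream seeded with `config$seed`, so identical configurations give
#' identical cohorts.
#'
#' @param config a [sim_config()].
#' @return list of `wmo_subject` objects; each holds `subject_id`,
#'   `trial_patterns` (parcel x trial x voxel), `trial_operations`,
#'   `rest_timeseries` (list of time x parcel runs), `task_timeseries`,
#'   `schedule` (trial onsets/durations in TRs and seconds),
#'   `questionnaires`, and the ground-truth `latent_difficulty`.
#' @export
generate_cohort <- function(config) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) stop("config must be a sim_config object")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  latent <- stats::rnorm(cfg$n_subjects)
  scales <- generate_questionnaires(latent, cfg)
  # cohort-level anatomy: the parcels' channel memberships are shared across
  # subjects (like real parcel anatomy); couplings perturb them per subject
  membership_base <- .base_memberships(cfg$network_labels, cfg$network_overlap)
  lapply(seq_len(cfg$n_subjects), function(i) {
    sp <- list(latent_difficulty = latent[i], membership_base = membership_base)
    tp <- generate_trial_patterns(sp, cfg)
    rest <- generate_rest_timeseries(sp, cfg)
    task <- .generate_task_series(tp, cfg)
    structure(list(
      subject_id = sprintf("sub-%03d", i),
      trial_patterns = tp$patterns,
      trial_operations = tp$trial_operations,
      executed_operations = tp$executed_operations,
      rest_timeseries = rest,
      task_timeseries = task$series,
      schedule = task$schedule,
      questionnaires = scales[i, , drop = FALSE],
      latent_difficulty = latent[i]
    ), class = "wmo_subject")
  })
}

# boxcar-level task series: each trial's parcel-mean feature held for
# trial_duration_tr TRs, gaps between trials, plus white noise
#' @keywords internal
#' @noRd
.generate_task_series <- function(tp, cfg) {
  Tn <- length(tp$trial_operations)
  dur <- cfg$trial_duration_tr; gap <- cfg$trial_gap_tr
  onsets <- (seq_len(Tn) - 1L) * (dur + gap)
  total <- Tn * (dur + gap)
  P <- dim(tp$patterns)[1]
  feat <- rowMeans(tp$patterns, dims = 2L)       # parcel x trial mean feature
  series <- matrix(stats::rnorm(total * P, sd = 0.5), total, P)
  for (t in seq_len(Tn)) {
    rows <- onsets[t] + seq_len(dur)
    series[rows, ] <- series[rows, ] + rep(feat[, t], each = dur)
  }
  schedule <- data.frame(
    trial = seq_len(Tn),
    operation = tp$trial_operations,
    onset_tr = onsets,
    duration_tr = dur,
    onset_s = onsets * cfg$tr_seconds,
    duration_s = dur * cfg$tr_seconds
  )
  list(series = series, schedule = schedule)
}

#' @export
print.wmo_subject <- function(x, ...) {
  d <- dim(x$trial_patterns)
  cat(sprintf("<wmo_subject %s: %d parcels x %d trials x %d voxels, %d rest runs>\n",
              x$subject_id, d[1], d[2], d[3], length(x$rest_timeseries)))
  invisible(x)
}
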