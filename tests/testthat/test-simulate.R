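test_that("default configuration encodes the study design", {
  cfg <- sim_config()
  expect_equal(cfg$n_subjects, 48L)
  expect_equal(cfg$n_parcels, 360L)
  expect_equal(cfg$trials_per_operation, 72L)
  expect_equal(cfg$trials_per_operation * cfg$n_operations, 288L)
  expect_equal(cfg$tr_seconds, 0.46)
  expect_equal(cfg$rest_run_timepoints, 750L)
  expect_equal(cfg$n_rest_runs, 2L)
  expect_equal(table(cfg$network_labels), table(default_network_labels(360)))
})

test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(n_parcels = 8, network_labels = factor(rep("V", 7))),
               "network_labels")
  bad <- default_geometry_templates()
  bad$DM[1, 2] <- 2  # asymmetric
  expect_error(sim_config(geometry_templates = bad), "symmetric")
  expect_error(sim_config(noise_shares = c(0.5, 0.5, 0.5)), "noise_shares")
  expect_error(sim_config(coupling = list(mixing = c(bogus = 0.5),
                                          variability = numeric(), label_noise = 0)),
               "mixing")
})

test_that("cohorts satisfy design conservation and determinism", {
  coh <- tiny_cohort()
  cfg <- tiny_config()
  expect_length(coh, cfg$n_subjects)
  for (s in coh[1:3]) {
    counts <- table(s$trial_operations)
    expect_true(all(counts == cfg$trials_per_operation))
    expect_equal(dim(s$trial_patterns),
                 c(cfg$n_parcels, 48L, cfg$voxels_per_parcel))
    expect_length(s$rest_timeseries, 2L)
    expect_equal(nrow(s$rest_timeseries[[1]]), cfg$rest_run_timepoints)
    expect_false(anyNA(s$trial_patterns))
  }
  # identical config + seed => identical cohort; different seed => different
  coh2 <- generate_cohort(tiny_config())
  expect_identical(coh[[2]]$trial_patterns, coh2[[2]]$trial_patterns)
  expect_identical(coh[[5]]$questionnaires, coh2[[5]]$questionnaires)
  coh3 <- generate_cohort(tiny_config(seed = 2L))
  expect_false(identical(coh[[1]]$trial_patterns, coh3[[1]]$trial_patterns))
})

test_that("noiseless prototypes reproduce the geometry templates", {
  cfg <- sim_config(n_subjects = 1, n_parcels = 4, voxels_per_parcel = 40,
                    trials_per_operation = 2, pattern_noise_sd = 1e-8,
                    mean_signal_snr = 0, seed = 3)
  set.seed(3)
  tp <- generate_trial_patterns(list(latent_difficulty = 0), cfg)
  for (p in 1:4) {
    net <- as.character(cfg$network_labels[p])
    # one trial per operation suffices: patterns are pure prototypes
    idx <- match(levels(tp$trial_operations), tp$trial_operations)
    protos <- t(tp$patterns[p, idx, ])
    emp <- cor(protos)
    expect_lt(max(abs(emp - cfg$geometry_templates[[net]])), 0.01)
  }
})

test_that("distinct-operation template yields lower off-diagonal similarity", {
  # FPC: four mutually dissimilar operations
  cfg <- sim_config(n_subjects = 1, n_parcels = 4, voxels_per_parcel = 24,
                    trials_per_operation = 24, seed = 7)
  set.seed(7)
  tp <- generate_trial_patterns(list(latent_difficulty = 0), cfg)
  p_fpc <- which(cfg$network_labels == "FPC")[1]
  sm <- trial_similarity(tp$patterns[p_fpc, , ])$values
  same <- outer(tp$trial_operations, tp$trial_operations, "==")
  diag(same) <- NA
  within <- mean(sm[which(same)], na.rm = TRUE)
  between <- mean(sm[which(!same)], na.rm = TRUE)
  expect_gt(within, between)
})

test_that("zero coupling leaves pattern statistics independent of the trait", {
  cfg <- sim_config(n_subjects = 30, n_parcels = 8, voxels_per_parcel = 12,
                    trials_per_operation = 12, rest_run_timepoints = 80,
                    seed = 11)
  coh <- generate_cohort(cfg)
  d <- vapply(coh, function(s) s$latent_difficulty, numeric(1))
  # summary statistic of each subject's patterns
  spread <- vapply(coh, function(s) sd(s$trial_patterns), numeric(1))
  expect_lt(abs(cor(spread, d)), 0.5)  # null correlation at n = 30
})

test_that("questionnaire totals live in their published ranges and recover the trait", {
  cfg <- sim_config(n_subjects = 200, n_parcels = 4, seed = 5)
  set.seed(5)
  d <- rnorm(200)
  q <- generate_questionnaires(d, cfg)
  expect_true(all(q$WBSI >= 15 & q$WBSI <= 75))
  expect_true(all(q$PSWQ >= 16 & q$PSWQ <= 80))
  expect_true(all(q$RRS_brooding >= 5 & q$RRS_brooding <= 20))

  # noiseless: composite z-average correlates 1 with the latent trait
  cfg0 <- sim_config(n_subjects = 50, n_parcels = 4, scale_noise_sd = 0, seed = 6)
  set.seed(6)
  d0 <- rnorm(50)
  q0 <- generate_questionnaires(d0, cfg0)
  comp0 <- composite_difficulty(q0)
  expect_gt(cor(comp0$composite, d0), 0.999)

  # noisy: attenuation matches loading / sqrt(loading^2 + sigma^2 / 3)
  sigma <- 1
  cfgn <- sim_config(n_subjects = 4000, n_parcels = 4, scale_noise_sd = sigma, seed = 8)
  set.seed(8)
  dn <- rnorm(4000)
  qn <- generate_questionnaires(dn, cfgn)
  compn <- composite_difficulty(qn)
  expected <- 1 / sqrt(1 + sigma^2 / 3)
  expect_lt(abs(cor(compn$composite, dn) - expected), 0.03)
})

test_that("rest series are standardized with network covariance structure", {
  cfg <- tiny_config()
  set.seed(9)
  rest <- generate_rest_timeseries(list(latent_difficulty = 0), cfg)
  y <- rest[[1]]
  expect_equal(colMeans(y), rep(0, ncol(y)), tolerance = 1e-10)
  expect_equal(apply(y, 2, sd), rep(1, ncol(y)), tolerance = 1e-10)
  r <- cor(y)
  labs <- cfg$network_labels
  same <- outer(labs, labs, "==") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[!same & upper.tri(r)]))

  # independent parcels: near-zero off-diagonal correlation
  set.seed(10)
  rest0 <- generate_rest_timeseries(list(latent_difficulty = 0), cfg,
                                    b_network = 0, b_global = 0)
  r0 <- cor(rest0[[1]])
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.08)
})
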