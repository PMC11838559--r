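test_that("composite score is the mean of sample z-scores", {
  # two-subject case, sample (n-1) sd convention: z = +/- 1/sqrt(2) * sqrt(2)
  tab <- data.frame(WBSI = c(30, 50), PSWQ = c(40, 60), RRS_brooding = c(8, 14))
  comp <- composite_difficulty(tab)
  # hand computation: each z = (x - mean) / sd = -/+ 0.7071068
  expect_equal(comp$z_wbsi, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(comp$composite, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # affine rescaling of a scale does not change the composite
  tab2 <- tab; tab2$PSWQ <- 3 * tab2$PSWQ + 7
  expect_equal(composite_difficulty(tab2)$composite, comp$composite)
  # zero-variance scale errors
  tab3 <- tab; tab3$WBSI <- c(40, 40)
  expect_error(composite_difficulty(tab3), "zero variance")
  expect_error(composite_difficulty(tab[, 1:2]), "missing")
})

test_that("screening regressions match an OLS oracle and apply BH-FDR", {
  set.seed(24)
  n <- 24
  subjects <- sprintf("s%02d", 1:n)
  comp <- data.frame(subject = subjects, composite = rnorm(n))
  cells <- expand.grid(condition = c("maintain", "replace", "suppress", "clear"),
                       network = c("V", "SM", "DM", "FPC"))
  mt <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(subject = subjects, condition = cells$condition[i],
               network = cells$network[i], eccentricity = rnorm(n))
  }))
  # one metric exactly equals the composite: R^2 = 1, p ~ 0
  mt$eccentricity[mt$condition == "suppress" & mt$network == "DM"] <-
    comp$composite[match(mt$subject[mt$condition == "suppress" & mt$network == "DM"],
                         comp$subject)]
  scr <- screen_regressions(mt, comp, family = "rsa_eccentricity")
  expect_equal(nrow(scr), 16L)
  hit <- scr[scr$condition == "suppress" & scr$network == "DM", ]
  expect_gt(hit$adjusted_r2, 0.999)
  expect_lt(hit$p_fdr, 1e-10)
  expect_true(hit$significant)

  # matrix-algebra oracle for one cell: normal equations
  cell <- scr[scr$condition == "maintain" & scr$network == "V", ]
  x <- mt$eccentricity[mt$condition == "maintain" & mt$network == "V"]
  y <- comp$composite
  xm <- cbind(1, x)
  beta <- solve(crossprod(xm), crossprod(xm, y))
  res <- y - xm %*% beta
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(crossprod(xm))[2, 2])
  t_o <- beta[2] / se
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  adj_o <- 1 - (1 - r2) * (n - 1) / (n - 2)
  expect_equal(cell$estimate, beta[2], tolerance = 1e-8)
  expect_equal(cell$t, t_o, tolerance = 1e-8)
  expect_equal(cell$F, t_o^2, tolerance = 1e-8)
  expect_equal(cell$adjusted_r2, adj_o, tolerance = 1e-8)

  # BH adjustment equals the step-up oracle
  p <- scr$p
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cummin_rev <- Inf
  for (i in m:1) {
    cummin_rev <- min(cummin_rev, p[o[i]] * m / i)
    adj[o[i]] <- min(1, cummin_rev)
  }
  expect_equal(scr$p_fdr, adj, tolerance = 1e-12)
  # monotone: adjusted p preserves the order of raw p
  expect_equal(order(scr$p_fdr[order(scr$p)]), seq_len(m))
  expect_error(screen_regressions(mt[mt$subject %in% subjects[1:5], ],
                                  comp[1:5, ], "f"), "10 subjects")
})

test_that("staged models report nested F-tests, adjusted R2 and VIF", {
  set.seed(25)
  n <- 48
  pc <- rnorm(n)
  m1 <- rnorm(n)
  m2 <- rnorm(n)
  fcm <- rnorm(n)
  y <- 0.5 * pc + 0.8 * m1 + 0.6 * fcm + rnorm(n)
  comp <- data.frame(subject = sprintf("s%02d", 1:n), composite = y)
  st <- hierarchical_stages(pc, data.frame(m1 = m1, m2 = m2), fcm, comp)
  expect_s3_class(st$stage1, "wmo_model_report")
  expect_length(st$stage2, 2L)
  expect_length(st$stage3, 2L)
  # oracle nested F for pc + m1 vs pc
  f_small <- lm(y ~ pc)
  f_big <- lm(y ~ pc + m1)
  rss0 <- sum(resid(f_small)^2); rss1 <- sum(resid(f_big)^2)
  f_o <- (rss0 - rss1) / (rss1 / (n - 3))
  expect_equal(st$stage2$m1$nested_comparison$F_change, f_o, tolerance = 1e-8)
  expect_equal(st$stage2$m1$adjusted_r2, summary(f_big)$adj.r.squared, tolerance = 1e-12)
  # informative predictor improves fit; VIF near 1 for independent predictors
  expect_lt(st$stage2$m1$nested_comparison$p_change, 0.01)
  expect_true(all(st$stage3$m1$vif < 1.5))
  # adding a pure-noise predictor: F_change small, adjusted R2 not inflated
  expect_gt(st$stage2$m2$nested_comparison$p_change, 0.01)
  expect_lt(st$stage2$m2$adjusted_r2 - st$stage1$adjusted_r2, 0.05)
  # stage3 >= stage2 >= stage1 in fit when couplings are real
  expect_gt(st$stage3$m1$adjusted_r2, st$stage2$m1$adjusted_r2)
  expect_gt(st$stage2$m1$adjusted_r2, st$stage1$adjusted_r2)
  # collinear design errors
  expect_error(hierarchical_stages(pc, data.frame(m1 = m1, m1b = m1), fcm, comp),
               "rank")
  tab <- model_report_table(st)
  expect_true(all(c("model_id", "F", "adjusted_r2", "F_change") %in% names(tab)))
})

test_that("the exploratory full model reports VIF and honest null fits", {
  set.seed(26)
  n <- 40
  pc <- rnorm(n)
  noise <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  comp <- data.frame(subject = seq_len(n), composite = rnorm(n))
  rep0 <- exploratory_full_model(noise, pc, comp)
  expect_lt(abs(rep0$adjusted_r2), 0.25)
  expect_length(rep0$vif, 5L)
  # predictors spanning the truth approach the generating R2 as noise -> 0
  y <- 0.6 * pc + 0.7 * noise[[1]] + rnorm(n, sd = 0.01)
  rep1 <- exploratory_full_model(noise, pc, data.frame(subject = seq_len(n),
                                                       composite = y))
  expect_gt(rep1$adjusted_r2, 0.99)
  expect_error(exploratory_full_model(as.data.frame(matrix(rnorm(40 * 39), 40, 39)),
                                      pc, comp), "predictors")
})

test_that("null additions of rest metrics add no explanatory power", {
  set.seed(27)
  n <- 48
  pc <- rnorm(n)
  task_m <- rnorm(n)
  y <- 0.6 * pc + 0.7 * task_m + rnorm(n)
  rest_m <- rnorm(n)  # resting metric, uncoupled
  comp <- data.frame(subject = sprintf("s%02d", 1:n), composite = y)
  st <- hierarchical_stages(pc, data.frame(task = task_m), rest_m, comp)
  expect_gt(st$stage3$task$nested_comparison$p_change, 0.01)
  expect_lt(st$stage3$task$adjusted_r2 - st$stage2$task$adjusted_r2, 0.03)
})
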