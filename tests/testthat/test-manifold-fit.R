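noiseless <- function(mech, n = 20, beta = 1, P_range = c(1e-4, 10),
                      seed = 5) {
  simulate_allelic_series(n, mech, noise_cv = 0, beta = beta,
                          P_range = P_range, P_spacing = "log-spaced",
                          seed = seed)
}

test_that("noiseless repression data give back the generating parameters", {
  sim <- noiseless("repression")
  fit <- fit_manifold(sim$data, "repression", n_starts = 3)
  expect_lt(rel_err(fit$estimates[["tsat"]], TSAT), 1e-6)
  expect_lt(rel_err(fit$estimates[["tbg"]], TBG), 1e-6)
  expect_lt(rel_err(fit$estimates[["F"]], F_CRP), 1e-6)
  expect_lt(max(rel_err(fit$P_by_promoter, sim$truth$P_by_promoter)), 1e-6)
  expect_lt(fit$loss, 1e-12)
  # dg view consistent with P estimates
  expect_equal(unname(fit$dg$dg_P),
               unname(dg_from_factor(fit$P_by_promoter)))
})

test_that("noiseless stabilization data recover alpha through alpha-prime", {
  sim <- noiseless("stabilization")
  fit <- fit_manifold(sim$data, "stabilization", F_tf = F_CRP,
                      n_starts = 3)
  expect_lt(rel_err(fit$estimates[["alpha"]], ALPHA_I), 1e-6)
  expect_equal(round(fit$dg$dg_alpha, 2), -4.05)
  expect_equal(fit$estimates[["alpha_prime"]],
               alpha_prime(fit$estimates[["alpha"]], F_CRP),
               tolerance = 1e-9)
})

test_that("fixed-parameter combinations all recover the remaining truth", {
  combos <- list(list(), list(tsat = TSAT), list(tbg = TBG),
                 list(tsat = TSAT, tbg = TBG))
  sim <- noiseless("repression", n = 12)
  for (fx in c(combos, list(list(F = F_CRP)))) {
    fit <- fit_manifold(sim$data, "repression", fixed = fx, n_starts = 2)
    expect_lt(rel_err(fit$estimates[["F"]], F_CRP), 1e-6)
    expect_lt(rel_err(fit$estimates[["tsat"]], TSAT), 1e-6)
  }
  sims <- noiseless("stabilization", n = 12)
  for (fx in combos) {
    fit <- fit_manifold(sims$data, "stabilization", fixed = fx,
                        F_tf = F_CRP, n_starts = 2)
    expect_lt(rel_err(fit$estimates[["alpha"]], ALPHA_I), 1e-6)
  }
})

test_that("the fitted model agrees with the brute-force state-sum oracle", {
  sim <- noiseless("repression", n = 10)
  fit <- fit_manifold(sim$data, "repression", n_starts = 2)
  pred <- oracle_rate("repression", fit$P_by_promoter,
                      F = fit$estimates[["F"]],
                      tsat = fit$estimates[["tsat"]],
                      tbg = fit$estimates[["tbg"]])
  expect_equal(unname(pred), sim$data$t_plus, tolerance = 1e-6)
  pred_m <- oracle_rate("minus", fit$P_by_promoter,
                        tsat = fit$estimates[["tsat"]],
                        tbg = fit$estimates[["tbg"]])
  expect_equal(unname(pred_m), sim$data$t_minus, tolerance = 1e-6)
})

test_that("unregulated data drive the regulatory parameter to its null", {
  sim <- noiseless("repression", n = 10)
  d <- sim$data
  d$t_plus <- d$t_minus  # no repression at all
  fit <- fit_manifold(d, "repression", n_starts = 2)
  expect_lt(fit$estimates[["F"]], 1e-3)
  fit2 <- fit_manifold(d, "stabilization", n_starts = 2)
  expect_equal(fit2$estimates[["alpha"]], 1, tolerance = 1e-3)
})

test_that("estimates are invariant under promoter row permutation", {
  sim <- simulate_allelic_series(15, "repression", noise_cv = 0.1,
                                 seed = 17)
  fit <- fit_manifold(sim$data, "repression", n_starts = 3)
  perm <- sim$data[c(8:15, 1:7), ]
  class(perm) <- class(sim$data)
  fitp <- fit_manifold(perm, "repression", n_starts = 3)
  expect_equal(fit$estimates, fitp$estimates, tolerance = 1e-8)
  expect_equal(fit$P_by_promoter[sort(names(fit$P_by_promoter))],
               fitp$P_by_promoter[sort(names(fitp$P_by_promoter))],
               tolerance = 1e-8)
})

test_that("the loss surface is minimized at the generating parameters", {
  sim <- noiseless("repression", n = 15)
  loss_at <- function(tsat, tbg, F, P) {
    sum(manifold_residuals(sim$data, "repression", tsat = tsat, tbg = tbg,
                           F = F, P = P)^2)
  }
  l0 <- loss_at(TSAT, TBG, F_CRP, sim$truth$P_by_promoter)
  set.seed(31)
  for (i in 1:100) {
    f <- 10^runif(3, -0.5, 0.5)
    Pf <- sim$truth$P_by_promoter * 10^runif(15, -0.2, 0.2)
    expect_gt(loss_at(TSAT * f[1], TBG * f[2], F_CRP * f[3], Pf), l0)
  }
})

test_that("too few promoters raise an identifiability error", {
  sim <- noiseless("repression", n = 3)
  expect_error(fit_manifold(sim$data, "repression", n_starts = 1),
               class = "allelic_identifiability_error")
  # n = 4 is the smallest identifiable full fit: 2n = 8 > n + 3 = 7
  sim4 <- noiseless("repression", n = 4)
  expect_s3_class(fit_manifold(sim4$data, "repression", n_starts = 2),
                  "manifold_fit")
})

test_that("joint fits share tsat and match independent fits at truth", {
  two <- list(
    a30 = simulate_allelic_series(12, "stabilization", alpha = 30,
                                  noise_cv = 0, P_spacing = "log-spaced",
                                  P_range = c(1e-4, 10), seed = 6),
    a700 = simulate_allelic_series(12, "stabilization", alpha = 700,
                                   noise_cv = 0, P_spacing = "log-spaced",
                                   P_range = c(1e-4, 10), seed = 7))
  jf <- joint_fit(lapply(two, `[[`, "data"), "stabilization",
                  F_tf = F_CRP, n_starts = 2)
  expect_lt(rel_err(jf$tsat, TSAT), 1e-5)
  expect_lt(rel_err(jf$fits$a30$estimates[["alpha"]], 30), 1e-5)
  expect_lt(rel_err(jf$fits$a700$estimates[["alpha"]], 700), 1e-5)
  # shared-tsat constraint is inactive at truth: joint total loss matches
  # the sum of independent losses (both ~ 0)
  indep <- lapply(two, function(s)
    fit_manifold(s$data, "stabilization", F_tf = F_CRP, n_starts = 2))
  expect_lt(jf$loss, sum(vapply(indep, function(f) f$loss, 0)) + 1e-10)
  # identical data across architectures give identical estimates
  same <- list(x = two$a30$data, y = two$a30$data)
  js <- joint_fit(same, "stabilization", F_tf = F_CRP, n_starts = 2)
  expect_equal(js$fits$x$estimates, js$fits$y$estimates, tolerance = 1e-7)
})

test_that("acceleration fits separate beta from alpha at fixed tsat", {
  simb <- simulate_allelic_series(20, "acceleration", alpha = 50, beta = 3,
                                  F = 5, noise_cv = 0,
                                  P_range = c(1e-3, 100),
                                  P_spacing = "log-spaced", seed = 8)
  fit <- fit_beta(simb$data, tsat = TSAT, F_tf = 5, n_starts = 3)
  expect_lt(rel_err(fit$estimates[["alpha"]], 50), 1e-5)
  expect_lt(rel_err(fit$estimates[["beta"]], 3), 1e-5)
  # beta fixed at 1 reduces exactly to the stabilization fit
  sims <- noiseless("stabilization", n = 12)
  f1 <- fit_manifold(sims$data, "acceleration", F_tf = F_CRP,
                     fixed = list(tsat = TSAT, beta = 1), n_starts = 2)
  f2 <- fit_manifold(sims$data, "stabilization", F_tf = F_CRP,
                     fixed = list(tsat = TSAT), n_starts = 2)
  expect_equal(f1$estimates[["alpha"]], f2$estimates[["alpha"]],
               tolerance = 1e-7)
  # data far from saturation leave beta weakly identified
  simw <- simulate_allelic_series(10, "stabilization", noise_cv = 0,
                                  P_range = c(1e-4, 1e-2),
                                  P_spacing = "log-spaced", seed = 9)
  expect_warning(fit_beta(simw$data, tsat = TSAT, F_tf = F_CRP,
                          n_starts = 2),
                 class = "allelic_weak_identifiability")
})

test_that("bootstrap ensembles are reproducible and tight on clean data", {
  sim <- simulate_allelic_series(15, "repression", noise_cv = 0.1,
                                 seed = 23)
  b1 <- bootstrap_manifold(sim$data, "repression", n_boot = 30, seed = 5,
                           n_starts = 3)
  b2 <- bootstrap_manifold(sim$data, "repression", n_boot = 30, seed = 5,
                           n_starts = 3)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$ci68, b2$ci68)
  expect_equal(b1$n_failed, 0)
  # noiseless data: bootstrap spread collapses
  sim0 <- noiseless("repression", n = 12)
  b0 <- bootstrap_manifold(sim0$data, "repression", n_boot = 20,
                           seed = 1, n_starts = 2)
  expect_lt(diff(b0$ci68$dg_F), 1e-5)
  # point estimate sits inside its own 68% interval
  expect_gte(b1$point$dg$dg_F, b1$ci68$dg_F[1] - 1e-9)
  expect_lte(b1$point$dg$dg_F, b1$ci68$dg_F[2] + 1e-9)
})

test_that("outlier detection flags injected promoters and only those", {
  sim <- noiseless("repression", n = 20)
  clean <- detect_outliers(sim$data, "repression", n_starts = 2)
  expect_identical(sum(clean$is_outlier), 0L)
  # multiply t+ of one regime-3 promoter by 10
  d <- sim$data
  b <- regime_boundaries("repression", TSAT, TBG, F_CRP)
  in3 <- which(sim$truth$P_by_promoter > b[2] * 3 &
                 sim$truth$P_by_promoter < b[3] / 3)
  victim <- unname(in3[ceiling(length(in3) / 2)])
  d$t_plus[victim] <- d$t_plus[victim] * 10
  flagged <- detect_outliers(d, "repression", n_starts = 2)
  expect_identical(which(flagged$is_outlier), victim)
  # refit on survivors restores the clean estimates
  refit <- fit_manifold(flagged, "repression", n_starts = 2)
  expect_lt(rel_err(refit$estimates[["F"]], F_CRP), 1e-6)
  expect_identical(refit$outliers_excluded, d$promoter_id[victim])
})

test_that("non-collapsing data raise a collapse-failure signal", {
  # t+ scattered a decade around the diagonal, independent of t-
  sim <- noiseless("repression", n = 24, P_range = c(1e-3, 1))
  d <- sim$data
  set.seed(3)
  d$t_plus <- d$t_minus * 10^runif(24, -1, 1)
  expect_error(detect_outliers(d, "repression", n_starts = 2),
               class = "allelic_collapse_failure")
})

test_that("titration analysis recovers the power-law exponent", {
  sim <- simulate_titration(n_promoters = 8, exponent = 1.41,
                            noise_cv = 0, seed = 3)
  tf <- titration_fit(sim$datasets, tsat = TSAT, tbg = TBG, n_starts = 2)
  expect_lt(abs(tf$exponent - 1.41), 1e-6)
  # slope invariant under concentration unit rescaling
  resc <- lapply(sim$datasets, function(d) {
    d$cAMP_uM <- d$cAMP_uM / 1000  # uM -> mM
    d
  })
  tf2 <- titration_fit(resc, tsat = TSAT, tbg = TBG, n_starts = 2)
  expect_equal(tf2$exponent, tf$exponent, tolerance = 1e-9)
  # flat truth gives slope 0
  sim0 <- simulate_titration(n_promoters = 8, exponent = 0,
                             noise_cv = 0, seed = 3)
  tf0 <- titration_fit(sim0$datasets, tsat = TSAT, tbg = TBG,
                       n_starts = 2)
  expect_lt(abs(tf0$exponent), 1e-6)
  # too few selected concentrations for a CI
  expect_error(titration_fit(sim$datasets[1:3], tsat = TSAT, tbg = TBG,
                             select = 2, n_starts = 2),
               class = "allelic_config_error")
})
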