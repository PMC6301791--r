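test_that("rate laws evaluate correctly and reduce to their limits", {
  # unbound promoter transcribes at background only
  expect_equal(t_minus(0, tsat = 15.1, tbg = 0.0023), 0.0023)
  expect_equal(t_minus(1, tsat = 10, tbg = 0.01), 5.01)
  # saturation limit
  expect_equal(t_minus(1e12, tsat = 15.1, tbg = 0.0023), 15.1 + 0.0023,
               tolerance = 1e-9)
  # repression with no TF equals the unregulated rate
  P <- 10^seq(-5, 2, length.out = 30)
  expect_equal(t_plus_repression(P, 0, 15.1, 0.0023),
               t_minus(P, 15.1, 0.0023))
  # direct evaluation against the independent state-sum oracle
  expect_equal(t_plus_repression(0.01, 23.9, 15.1, 0.0023),
               oracle_rate("repression", 0.01, F = 23.9,
                           tsat = 15.1, tbg = 0.0023),
               tolerance = 1e-14)
  expect_equal(t_plus_repression(0.01, 23.9, 15.1, 0.0023), 0.008362,
               tolerance = 1e-4)
  # repression never exceeds the unregulated rate
  expect_true(all(t_plus_repression(P, 23.9, 15.1, 0.0023) <=
                    t_minus(P, 15.1, 0.0023)))
  # deep parallel regime: t+/t- -> 1/(1+F)
  expect_equal(t_plus_repression(1e-2, 23.9, 15.1, 1e-8) /
                 t_minus(1e-2, 15.1, 1e-8),
               1 / 24.9, tolerance = 0.02)
})

test_that("renormalized cooperativity and acceleration behave as derived", {
  expect_equal(alpha_prime(1, 17.3), 1)
  ap <- alpha_prime(712, 23.9)
  expect_equal(ap, (1 + 712 * 23.9) / 24.9)
  expect_equal(round(100 * (712 - ap) / 712), 4)  # within 4% of alpha
  expect_equal(alpha_prime(5, 1e12), 5, tolerance = 1e-9)
  expect_true(all(alpha_prime(c(2, 10, 700), 3) <= c(2, 10, 700)))

  expect_equal(beta_prime(37, 1, 2.2), 1)
  expect_equal(beta_prime(100, 2, 10), 2001 / 1001)
  expect_equal(beta_prime(1e9, 3, 1e3), 3, tolerance = 1e-5)
})

test_that("state-sum and renormalized forms are algebraically identical", {
  set.seed(42)
  n <- 2000
  P <- 10^runif(n, -4, 3)
  F <- 10^runif(n, -4, 3)
  alpha <- 10^runif(n, -2, 3)
  beta <- 10^runif(n, -2, 2)
  a3 <- t_plus_activation(P, F, alpha, 15.1, 0.0023, form = "states")
  a4 <- t_plus_activation(P, F, alpha, 15.1, 0.0023, form = "renormalized")
  expect_lt(max(rel_err(a4, a3)), 1e-12)
  a6 <- t_plus_acceleration(P, F, alpha, beta, 15.1, 0.0023,
                            form = "states")
  a7 <- t_plus_acceleration(P, F, alpha, beta, 15.1, 0.0023,
                            form = "renormalized")
  expect_lt(max(rel_err(a7, a6)), 1e-12)
  # beta = 1 reduces acceleration to stabilization
  expect_equal(t_plus_acceleration(P, F, alpha, 1, 15.1, 0.0023), a3)
  # alpha = 1: regulation disappears, t+ = t-
  expect_equal(t_plus_activation(P, F, 1, 15.1, 0.0023),
               t_minus(P, 15.1, 0.0023))
})

test_that("all rate laws are monotone in P, bounded, and match the oracle", {
  P <- 10^seq(-6, 4, length.out = 200)
  cases <- list(
    list(mech = "repression", F = 23.9, alpha = 1, beta = 1),
    list(mech = "stabilization", F = 23.9, alpha = 712, beta = 1),
    list(mech = "acceleration", F = 5, alpha = 50, beta = 3))
  for (cs in cases) {
    tp <- switch(cs$mech,
      repression = t_plus_repression(P, cs$F, 15.1, 0.0023),
      stabilization = t_plus_activation(P, cs$F, cs$alpha, 15.1, 0.0023),
      acceleration = t_plus_acceleration(P, cs$F, cs$alpha, cs$beta,
                                         15.1, 0.0023))
    expect_true(all(diff(tp) > 0), info = cs$mech)
    bp <- beta_prime(cs$alpha, cs$beta, cs$F)
    expect_true(all(tp >= 0.0023 & tp < bp * 15.1 + 0.0023),
                info = cs$mech)
    ref <- oracle_rate(cs$mech, P, cs$F, cs$alpha, cs$beta, 15.1, 0.0023)
    expect_equal(tp, ref, tolerance = 1e-12, info = cs$mech)
  }
  tm <- t_minus(P, 15.1, 0.0023)
  expect_equal(tm, oracle_rate("minus", P, tsat = 15.1, tbg = 0.0023),
               tolerance = 1e-12)
  # saturation: both channels meet at tsat + tbg under stabilization
  expect_equal(t_plus_activation(1e9, 23.9, 712, 15.1, 0.0023),
               t_minus(1e9, 15.1, 0.0023), tolerance = 1e-6)
})

test_that("state probabilities normalize and weight states correctly", {
  expect_equal(state_probabilities(0, 0),
               c(unbound = 1, tf_bound = 0, rnap_bound = 0,
                 doubly_bound = 0))
  expect_equal(unname(state_probabilities(1, 1, 1)), rep(0.25, 4))
  set.seed(7)
  for (i in 1:25) {
    p <- state_probabilities(10^runif(1, -3, 3), 10^runif(1, -3, 3),
                             10^runif(1, -2, 3))
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  # three-state repression model forbids the ternary complex
  p3 <- state_probabilities(2, 5, doubly_bound = FALSE)
  expect_identical(unname(p3["doubly_bound"]), 0)
  expect_equal(sum(p3), 1)
})

test_that("free-energy conversions follow -kBT ln(x) and roundtrip", {
  expect_equal(dg_from_factor(1), 0)
  # printed two-decimal values under the 1.62 convention
  expect_equal(round(dg_from_factor(23.9), 2), -1.96)
  expect_equal(round(dg_from_factor(712), 2), -4.05)
  set.seed(11)
  x <- 10^runif(50, -6, 6)
  expect_lt(max(rel_err(factor_from_dg(dg_from_factor(x)), x)), 1e-12)
  y <- 10^runif(50, -6, 6)
  expect_equal(dg_from_factor(x * y), dg_from_factor(x) + dg_from_factor(y))
  expect_error(dg_from_factor(0), class = "allelic_domain_error")
  expect_error(dg_from_factor(-3), class = "allelic_domain_error")
  # unit convention: physical kBT at 310.15 K gives 1.62 kBT per kcal/mol
  expect_equal(round(1 / kbt_kcal(310.15), 2), 1.62)
})

test_that("negative inputs raise domain errors", {
  expect_error(t_minus(-1, 10, 0.01), class = "allelic_domain_error")
  expect_error(t_plus_repression(1, -2, 10, 0.01),
               class = "allelic_domain_error")
  expect_error(t_plus_activation(1, 1, -1, 10, 0.01),
               class = "allelic_domain_error")
  expect_error(t_minus(1, -10, 0.01), class = "allelic_domain_error")
})
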