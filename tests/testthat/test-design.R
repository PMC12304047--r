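test_that("time grids follow n = f*D + 1 with endpoints 0 and D", {
  expect_equal(time_grid(4, 1), c(0, 1, 2, 3, 4))
  expect_equal(time_grid(1, 4), c(0, 0.25, 0.5, 0.75, 1))
  g8 <- time_grid(8, 1)
  expect_length(g8, 9L)
  expect_equal(g8[9L], 8)

  set.seed(11)
  for (i in 1:50) {
    f <- sample(1:6, 1)
    D <- sample(1:10, 1)
    g <- time_grid(D, f)
    expect_length(g, f * D + 1)
    expect_equal(g[1L], 0)
    expect_equal(g[length(g)], D)
    expect_equal((length(g) - 1) / f, D)
  }
  expect_error(time_grid(1.5, 2.1), "whole number")
})

test_that("time transformation is the identity or a shifted log, order preserving", {
  expect_identical(transform_times(c(0, 1, 2), FALSE, 0), c(0, 1, 2))
  expect_equal(transform_times(c(1, 2, 4), TRUE),
               c(0, 0.6931472, 1.3862944), tolerance = 1e-6)
  expect_equal(transform_times(c(0, 5, 13, 638), TRUE, log_shift = 1),
               c(0, 1.7917595, 2.6390573, 6.4599045), tolerance = 1e-6)
  expect_error(transform_times(c(0, 5, 13), TRUE, 0), "time 0")
  expect_error(transform_times(c(3, 2, 1), FALSE), "strictly increasing")

  set.seed(12)
  for (i in 1:50) {
    t <- sort(runif(sample(2:9, 1), 0.01, 50))
    out <- transform_times(t, TRUE, runif(1, 0, 2))
    expect_true(all(diff(out) > 0))
  }
})

test_that("effect size converts to the interaction coefficient delta*sqrt(var_u1)", {
  expect_equal(beta2_from_effect(0.8, 0.001), 0.0253, tolerance = 2e-3)
  expect_equal(beta2_from_effect(0.8, 0.001), 0.8 * sqrt(0.001))
  expect_equal(beta2_from_effect(0.40, 0.0030), 0.0219, tolerance = 2e-3)
  expect_identical(beta2_from_effect(0, 0.37), 0)
  expect_error(beta2_from_effect(-0.4, 0.1), "direction")
})

test_that("closed-form interaction SE collapses, scales and orders correctly", {
  d <- growth_design(t_points = c(0, 1, 2), var_e = 0.02, var_u0 = 0,
                     var_u1 = 0, eff_size = 0)
  # no slope variance: SE^2 = 4 var_e / (N * sum(t^2)) in the uncentered form
  expect_equal(analytic_se_beta2(d, 100, centered = FALSE),
               sqrt(4 * 0.02 / (100 * 5)), tolerance = 1e-12)
  expect_equal(analytic_se_beta2(d, 100, centered = FALSE), 0.012649,
               tolerance = 1e-4)

  d1 <- example1_design()
  expect_equal(analytic_se_beta2(d1, 400) / analytic_se_beta2(d1, 200),
               1 / sqrt(2), tolerance = 1e-12)

  set.seed(13)
  for (i in 1:30) {
    d <- growth_design(t_points = sort(runif(4, 0, 6)),
                       var_e = runif(1, 0.01, 2),
                       var_u0 = runif(1, 0, 1), var_u1 = runif(1, 0, 0.5),
                       eff_size = 0.3)
    for (cen in c(TRUE, FALSE)) {
      expect_lt(analytic_se_beta2(d, 200, cen), analytic_se_beta2(d, 100, cen))
      d_bige <- d; d_bige$var_e <- d$var_e * 2
      d_bigu <- d; d_bigu$var_u1 <- d$var_u1 + 0.2
      expect_gt(analytic_se_beta2(d_bige, 100, cen),
                analytic_se_beta2(d, 100, cen))
      expect_gt(analytic_se_beta2(d_bigu, 100, cen),
                analytic_se_beta2(d, 100, cen))
    }
  }
})

test_that("effective sample size respects the [N, N*n] clamp and its limits", {
  # independent observations: every measurement counts
  d_ind <- growth_design(t_points = 0:4, var_e = 0.5, var_u0 = 0,
                         var_u1 = 0, cov_u01 = 0, eff_size = 0)
  expect_equal(effective_sample_size(d_ind, 100), 500)

  # hand arithmetic of the closed form for a non-clamped case:
  # w = (var_e + var_u0 + mean(t^2) var_u1) / (var_e + var_u1 * Sc)
  d <- growth_design(t_points = 0:4, var_e = 0.02, var_u0 = 0.001,
                     var_u1 = 0.1, eff_size = 0.3)
  w <- (0.02 + 0.001 + 6 * 0.1) / (0.02 + 0.1 * 10)
  expect_equal(effective_sample_size(d, 100), w * 500, tolerance = 1e-10)

  set.seed(14)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    vu0 <- runif(1, 0, 2); vu1 <- runif(1, 0, 1)
    d <- growth_design(t_points = sort(runif(n, 0, 8)),
                       var_e = runif(1, 0.01, 3),
                       var_u0 = vu0, var_u1 = vu1,
                       cov_u01 = runif(1, -1, 1) * sqrt(vu0 * vu1),
                       eff_size = 0.2)
    N <- sample(4:500, 1)
    neff <- effective_sample_size(d, N)
    expect_gte(neff, N)
    expect_lte(neff, N * n)
  }
})

test_that("prior fraction is J / N_eff", {
  expect_equal(b_fraction(1, 100), 0.01)
  expect_equal(b_fraction(2, 100), 0.02)
  expect_equal(b_fraction(3, 100), 0.03)
  expect_error(b_fraction(4, 100))
})

test_that("design validation rejects inconsistent inputs", {
  expect_error(growth_design(t_points = c(0, 0, 1)), "strictly increasing")
  expect_error(growth_design(t_points = 3), "at least two")
  expect_error(growth_design(var_u0 = 0.01, var_u1 = 0.01, cov_u01 = 0.5),
               "semi-definite")
  expect_error(growth_design(eff_size = -0.3), "direction")
  expect_error(growth_design(t_points = c(0, 1), log_growth = TRUE),
               "log_shift")
  d <- growth_design(duration = 4, frequency = 2)
  expect_equal(d$raw_times, seq(0, 4, by = 0.5))
})
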