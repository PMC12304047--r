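test_that("fit and complexity match independent density evaluations", {
  # H0: densities at zero under posterior and fractional prior
  fc <- fit_and_complexity(0.5, 0.1, 0.01, "H0")
  expect_equal(fc[["fit"]], dnorm(0, 0.5, sqrt(0.1)), tolerance = 1e-12)
  expect_equal(fc[["complexity"]], dnorm(0, 0, sqrt(0.1 / 0.01)),
               tolerance = 1e-12)
  # H1: upper-tail masses; complexity exactly one half
  fc1 <- fit_and_complexity(0.5, 0.1, 0.01, "H1")
  expect_identical(fc1[["complexity"]], 0.5)
  expect_equal(fc1[["fit"]], pnorm(0, 0.5, sqrt(0.1), lower.tail = FALSE),
               tolerance = 1e-12)
  # boundary estimate: symmetric posterior
  expect_equal(fit_and_complexity(0, 0.2, 0.05, "H1")[["fit"]], 0.5)
  expect_error(fit_and_complexity(0.5, 0.1, 0, "H0"), "b")
  expect_error(fit_and_complexity(0.5, 0.1, -1, "H0"), "b")
})

test_that("quadrature reproduces fit1 and comp0 to 1e-8", {
  for (est in c(-0.4, 0, 0.7)) {
    for (b in c(0.01, 0.2)) {
      fc1 <- fit_and_complexity(est, 0.1, b, "H1")
      num <- integrate(dnorm, 0, Inf, mean = est, sd = sqrt(0.1),
                       rel.tol = 1e-12)$value
      expect_equal(fc1[["fit"]], num, tolerance = 1e-8)
      fc0 <- fit_and_complexity(est, 0.1, b, "H0")
      # density as the limit of shrinking-interval prior mass
      eps <- 1e-6
      num0 <- integrate(dnorm, -eps, eps, mean = 0, sd = sqrt(0.1 / b),
                        rel.tol = 1e-12)$value / (2 * eps)
      expect_equal(fc0[["complexity"]], num0, tolerance = 1e-8)
    }
  }
})

test_that("the worked example reproduces the published Bayes factors", {
  bf <- lapply(c(0.01, 0.02, 0.03), function(b) aafbf(0.5, 0.1, b))
  expect_equal(vapply(bf, `[[`, 0, "comp0"), c(0.126, 0.178, 0.219),
               tolerance = 5e-3)
  expect_equal(bf[[1]]$fit0, 0.36, tolerance = 5e-3)
  expect_equal(vapply(bf, `[[`, 0, "bf_0u"), c(2.86, 2.02, 1.64),
               tolerance = 0.01)
  expect_equal(bf[[1]]$bf_1u, 1.88, tolerance = 5e-3)
  expect_equal(vapply(bf, `[[`, 0, "bf_01"), c(1.52, 1.07, 0.87),
               tolerance = 0.01)
})

test_that("BF identities hold: reciprocal, ratio and complement forms", {
  set.seed(31)
  for (i in 1:100) {
    est <- rnorm(1, 0, 2)
    se2 <- runif(1, 0.001, 2)
    b <- runif(1, 1e-4, 1)
    x <- aafbf(est, se2, b)
    expect_equal(x$bf_10, 1 / x$bf_01, tolerance = 1e-12)
    expect_equal(x$bf_01, x$bf_0u / x$bf_1u, tolerance = 1e-12)
    if (x$fit1 < 1 - 1e-9 && x$fit1 > 1e-9) {
      # the naive ratio loses precision once fit1 rounds toward 0 or 1;
      # the log-scale computation remains exact there
      expect_equal(x$bf_1c, x$fit1 / (1 - x$fit1), tolerance = 1e-6)
      expect_lt(x$fit1, 1)
    }
    expect_true(all(c(x$bf_0u, x$bf_1u, x$bf_01, x$bf_1c) > 0))
    expect_gt(x$fit1, 0); expect_lte(x$fit1, 1)
    # Savage-Dickey: BF_0u is the posterior/prior density ratio at zero
    expect_equal(x$bf_0u,
                 dnorm(0, est, sqrt(se2)) / dnorm(0, 0, sqrt(se2 / b)),
                 tolerance = 1e-10)
  }
})

test_that("inequality BFs are independent of b; BF_0u decreases in b", {
  set.seed(32)
  for (i in 1:50) {
    est <- rnorm(1, 0.2, 1)
    se2 <- runif(1, 0.01, 1)
    b <- runif(1, 1e-4, 0.3)
    x1 <- aafbf(est, se2, b)
    x2 <- aafbf(est, se2, 2 * b)
    x3 <- aafbf(est, se2, 3 * b)
    expect_equal(x1$bf_1u, x2$bf_1u, tolerance = 1e-12)
    expect_equal(x1$bf_1u, x3$bf_1u, tolerance = 1e-12)
    expect_equal(x1$bf_1c, x2$bf_1c, tolerance = 1e-12)
    expect_equal(x1$bf_1c, x3$bf_1c, tolerance = 1e-12)
    expect_gt(x1$bf_0u, x2$bf_0u)
    expect_gt(x2$bf_0u, x3$bf_0u)
  }
})

test_that("BF_1u is bounded by 1/comp1 = 2 and equals 1 at the boundary", {
  set.seed(33)
  for (i in 1:200) {
    x <- aafbf(rnorm(1, 0, 5), runif(1, 1e-4, 3), runif(1, 1e-4, 1))
    # the bound is strict in exact arithmetic; fit1 can round to 1 in
    # double precision, so allow equality at the representable limit
    expect_lte(x$bf_1u, 2)
  }
  x_mod <- aafbf(0.8, 0.25, 0.1)  # moderate evidence: strictly inside
  expect_lt(x_mod$bf_1u, 2)
  x0 <- aafbf(0, 0.37, 0.05)
  expect_equal(x0$bf_1u, 1, tolerance = 1e-12)
  expect_equal(x0$bf_1c, 1, tolerance = 1e-12)
})

test_that("a negative-direction hypothesis is evaluated by sign reflection", {
  a <- aafbf(-0.4, 0.05, 0.02, direction = "negative")
  b <- aafbf(0.4, 0.05, 0.02, direction = "positive")
  for (f in c("bf_0u", "bf_1u", "bf_01", "bf_1c", "fit1", "comp0")) {
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  }
})

test_that("extreme standardized estimates do not underflow", {
  x <- aafbf(50, 0.01, 0.001)  # z = 500
  expect_true(is.finite(log(x$bf_1c)) || x$bf_1c == Inf)
  expect_gt(x$bf_1u, 1.999999)
  lb <- growthssd:::log_bf_for_truth(50, 0.01, 0.001, "H1", "alt")
  expect_true(is.finite(lb))
  expect_gt(lb, 0)
})
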