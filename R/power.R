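# Bayesian power: Monte Carlo estimation and a deterministic
# fixed-standard-error oracle.

# Simulate and fit m datasets under one generating hypothesis; returns a
# tibble of interaction estimates with flags. Non-converging datasets are
# resimulated once from a fresh child stream, then excluded.
fit_batch <- function(design, n_subjects, truth, m, master_seed,
                      method = "REML") {
  cond <- allocate_conditions(n_subjects)
  n0 <- sum(cond == 0L)
  consts <- fit_constants(design$times, n0, n_subjects - n0,
                          method == "REML")
  est <- se2 <- numeric(m)
  ok <- conv <- logical(m)
  sing <- logical(m)
  for (k in seq_len(m)) {
    core <- NULL
    for (attempt in 0:1) {
      seed <- child_seed(master_seed, truth, n_subjects, k, attempt)
      sim <- simulate_outcome_matrix(design, n_subjects, truth, seed)
      core <- fit_balanced_core(fit_stats(sim$y, consts), consts,
                                method == "REML")
      if (isTRUE(core$ok) && isTRUE(core$converged)) break
    }
    good <- isTRUE(core$ok) && isTRUE(core$converged)
    ok[k] <- good
    if (isTRUE(core$ok)) {
      est[k] <- core$beta[4L]
      se2[k] <- core$se2_beta2
      sing[k] <- isTRUE(core$singular)
    }
  }
  tibble(k = seq_len(m), beta2_hat = est, se2 = se2,
         ok = ok, singular = sing)
}

# Power for one (truth, J) from a batch of fitted estimates.
power_from_batch <- function(batch, design, n_subjects, fraction,
                             truth) {
  neff <- effective_sample_size(design, n_subjects)
  b <- b_fraction(fraction, neff)
  use <- batch$ok
  if (!any(use)) {
    abort(sprintf(
      "all %d model fits failed at N = %d; the design is degenerate.",
      nrow(batch), n_subjects))
  }
  est <- batch$beta2_hat[use]
  if (design$direction == "negative") est <- -est
  lbf <- log_bf_for_truth(est, batch$se2[use], b, truth, design$test)
  mean(lbf > log(design$bf_thresh))
}

#' Monte Carlo estimate of Bayesian power
#'
#' Simulates `m` trials under each requested true hypothesis, fits each
#' with the balanced-design estimator, evaluates the AAFBF of the true
#' hypothesis against the configured comparison at
#' \eqn{b = J/N_{eff}}, and reports the proportion of Bayes factors
#' exceeding the threshold: \eqn{\eta_0} (probability of compelling
#' evidence for \eqn{H_0} when it is true), \eqn{\eta_1} (likewise for
#' \eqn{H_1}) and \eqn{\eta = \min} over the requested set. Fitted
#' estimates are computed once and reused across `fractions`, since the
#' posterior (hence the fit) does not depend on \eqn{b}.
#'
#' @param design A [growth_design()].
#' @param n_subjects Total number of subjects (at least 4).
#' @param fractions Subset of `1:3`; defaults to the design's fraction
#'   (or `1:3` when the design asks for a sensitivity analysis).
#' @param m Number of Monte Carlo datasets per hypothesis.
#' @param seed Master seed; defaults to the design's.
#' @return A `bayes_power` object: tibble with one row per fraction and
#'   columns `fraction`, `eta0`, `eta1`, `eta`, plus attributes
#'   `m_effective` and `excluded`.
#' @examples
#' d <- growth_design(eff_size = 0.4, var_u1 = 0.003, m = 50)
#' estimate_power(d, 60, seed = 1)
#' @export
estimate_power <- function(design, n_subjects,
                           fractions = requested_fractions(design),
                           m = design$m, seed = design$seed) {
  stopifnot(inherits(design, "growth_design"), n_subjects >= 4)
  if (is.null(seed)) seed <- 0L
  if (design$test == "Hu" && design$bf_thresh >= 2) {
    warn("BF_1u is bounded above by 2 (fit < 1, complexity 0.5); with test = \"Hu\" and a threshold >= 2 the power for H1 is identically zero.")
  }
  truths <- requested_truths(design)
  batches <- lapply(setNames(truths, truths), function(h) {
    fit_batch(design, n_subjects, h, m, seed)
  })
  rows <- purrr::map_dfr(fractions, function(j) {
    eta0 <- if ("H0" %in% truths) {
      power_from_batch(batches$H0, design, n_subjects, j, "H0")
    } else NA_real_
    eta1 <- if ("H1" %in% truths) {
      power_from_batch(batches$H1, design, n_subjects, j, "H1")
    } else NA_real_
    tibble(fraction = as.integer(j), eta0 = eta0, eta1 = eta1,
           eta = min(c(eta0, eta1), na.rm = TRUE))
  })
  structure(rows,
            class = c("bayes_power", class(rows)),
            n_subjects = n_subjects,
            m_effective = vapply(batches, function(b) sum(b$ok), 0L),
            excluded = vapply(batches, function(b) sum(!b$ok), 0L),
            bf_thresh = design$bf_thresh, test = design$test)
}

#' @export
print.bayes_power <- function(x, ...) {
  cat(sprintf("<bayes_power: N = %d, BF threshold %g, test %s>\n",
              attr(x, "n_subjects"), attr(x, "bf_thresh"), attr(x, "test")))
  print(as_tibble(x), ...)
  excl <- attr(x, "excluded")
  if (any(excl > 0)) {
    cat("  excluded fits:", paste(names(excl), excl, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.bayes_power <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), c("eta0", "eta1"),
                      names_to = "hypothesis", values_to = "power") |>
    dplyr::mutate(hypothesis = ifelse(.data$hypothesis == "eta0",
                                      "H0", "H1"))
}

#' @export
autoplot.bayes_power <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$power), ],
                  ggplot2::aes(x = factor(.data$fraction), y = .data$power,
                               fill = .data$hypothesis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fraction multiplier J", y = "Bayesian power",
                  fill = "true hypothesis") +
    ggplot2::ylim(0, 1)
}

# log BF favoring `truth` as a function of the standardized estimate z,
# holding the standard error at its analytic value. Used by the oracle.
oracle_log_bf <- function(z, b, truth, test) {
  log_bf_for_truth(z, 1, b, truth, test)
}

#' Deterministic power oracle with fixed standard error
#'
#' Approximates Bayesian power without any model fitting: the sampling
#' distribution of \eqn{\hat\beta_2} is taken as normal with mean equal to
#' the generating coefficient and standard deviation from
#' [analytic_se_beta2()], the standard error inside the Bayes factor is
#' held at the same analytic value, and the exceedance region of the BF
#' (monotone or an interval in the standardized estimate) is located by
#' root finding. The Monte Carlo pipeline estimates the standard error per
#' dataset, so the two agree only up to that approximation (closely, at
#' the sample sizes of interest).
#'
#' @inheritParams estimate_power
#' @param truth Generating hypothesis.
#' @param fraction Multiplier \eqn{J}; ignored when `b` is given.
#' @param b Prior fraction; defaults to `fraction / effective_sample_size`.
#' @return The oracle power, a scalar in \eqn{[0, 1]}.
#' @export
analytic_power <- function(design, n_subjects, truth = c("H1", "H0"),
                           fraction = design$fraction, b = NULL) {
  truth <- match.arg(truth)
  se <- analytic_se_beta2(design, n_subjects)
  if (is.null(b)) {
    b <- b_fraction(fraction, effective_sample_size(design, n_subjects))
  }
  zbar <- if (truth == "H1") design$beta2 / se else 0
  thres <- log(design$bf_thresh)
  test <- design$test

  if (truth == "H0" && test %in% c("Hc", "Hu")) {
    # BF_0u = exp(-z^2/2)/sqrt(b): an interval around zero (or empty)
    if (log(1 / sqrt(b)) <= thres) return(0)
    zb <- sqrt(-2 * (thres + 0.5 * log(b)))
    return(pnorm(zb) - pnorm(-zb))
  }
  if (truth == "H1" && test == "Hu" && design$bf_thresh >= 2) return(0)

  f <- function(z) oracle_log_bf(z, b, truth, test) - thres
  lo <- -38; hi <- 38
  # BF for H1 is increasing in z, for H0 (alt) decreasing
  increasing <- truth == "H1"
  if (increasing) {
    if (f(lo) > 0) return(1)
    if (f(hi) < 0) return(0)
    zstar <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    pnorm(zstar - zbar, lower.tail = FALSE)
  } else {
    if (f(lo) < 0) return(0)
    if (f(hi) > 0) return(1)
    zstar <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    pnorm(zstar - zbar)
  }
}

#' Power over a grid of durations and observation frequencies
#'
#' Sweeps Monte Carlo power over study durations and measurement
#' frequencies at a fixed number of subjects, for reports on trading
#' design factors against each other.
#'
#' @inheritParams estimate_power
#' @param durations Vector of study durations.
#' @param frequencies Vector of observations per time unit.
#' @param truth Generating hypothesis for the reported power.
#' @return A `power_grid` tibble with columns `duration`, `frequency`,
#'   `n_occasions`, `power`.
#' @export
power_grid <- function(design, n_subjects, durations, frequencies,
                       truth = "H1", m = design$m, seed = design$seed) {
  grid <- tidyr::expand_grid(duration = durations, frequency = frequencies)
  rows <- purrr::pmap_dfr(grid, function(duration, frequency) {
    d <- design
    d$raw_times <- time_grid(duration, frequency)
    d$times <- transform_times(d$raw_times, d$log_growth, d$log_shift)
    d$hypothesis <- if (truth == "H1") "H1" else "H0"
    pw <- estimate_power(d, n_subjects, fractions = design$fraction,
                         m = m, seed = seed)
    tibble(duration = duration, frequency = frequency,
           n_occasions = length(d$times),
           power = if (truth == "H1") pw$eta1[1L] else pw$eta0[1L])
  })
  class(rows) <- c("power_grid", class(rows))
  rows
}

#' @export
autoplot.power_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$duration, y = .data$power,
                               colour = factor(.data$frequency))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "study duration D", y = "Bayesian power",
                  colour = "frequency f") +
    ggplot2::ylim(0, 1)
}
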