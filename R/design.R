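#' Build an equally spaced measurement time grid
#'
#' Computes the measurement occasions of a study of duration `duration`
#' (in study time units, e.g. years) observed `frequency` times per unit,
#' with the first measurement at baseline (time zero). A design with
#' duration \eqn{D} and frequency \eqn{f} has \eqn{n = fD + 1} occasions at
#' times \eqn{T_j = (j - 1)/f}, terminating at time \eqn{D}.
#'
#' @param duration Positive study duration \eqn{D}.
#' @param frequency Positive number of observations per time unit \eqn{f}.
#'   The product `frequency * duration` must be a whole number, since a
#'   design cannot have a fractional number of measurement occasions.
#' @return Numeric vector of length `frequency * duration + 1`, from 0 to
#'   `duration`.
#' @examples
#' time_grid(4, 1)   # 0 1 2 3 4
#' time_grid(1, 4)   # 0 0.25 0.5 0.75 1
#' @export
time_grid <- function(duration, frequency) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(frequency), length(frequency) == 1L, frequency > 0)
  fd <- frequency * duration
  if (abs(fd - round(fd)) > 1e-8) {
    abort(sprintf(
      "`frequency * duration` = %g is not a whole number; the design would have a fractional number of occasions. Pass explicit time points instead.",
      fd))
  }
  n <- round(fd) + 1L
  (seq_len(n) - 1) / frequency
}

#' Transform measurement times for log-linear growth
#'
#' Log-linear growth is linear growth on the natural-log time scale. When
#' `log_growth` is `TRUE` the times are mapped to `log(times + log_shift)`;
#' otherwise they are returned unchanged. A grid containing time zero
#' requires a positive `log_shift` (a shift of 1 keeps baseline at 0 on the
#' transformed scale).
#'
#' @param times Strictly increasing numeric vector of measurement times.
#' @param log_growth Logical; apply the log transform?
#' @param log_shift Non-negative offset added inside the logarithm.
#' @return Numeric vector of the same length, strictly increasing.
#' @examples
#' transform_times(c(1, 2, 4), log_growth = TRUE)
#' transform_times(c(0, 5, 13, 638), log_growth = TRUE, log_shift = 1)
#' @export
transform_times <- function(times, log_growth = FALSE, log_shift = 0) {
  check_times(times)
  if (!isTRUE(log_growth)) return(times)
  stopifnot(is.numeric(log_shift), length(log_shift) == 1L, log_shift >= 0)
  shifted <- times + log_shift
  if (any(shifted <= 0)) {
    bad <- times[shifted <= 0][1L]
    abort(sprintf(
      "log-linear growth requires `time + log_shift > 0`, but time %g gives %g. Supply a positive `log_shift` (a shift of 1 is a sensible default for grids starting at 0).",
      bad, bad + log_shift))
  }
  log(shifted)
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 2L) {
    abort("`times` must be a numeric vector with at least two measurement occasions.")
  }
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.")
  }
  if (times[1L] < 0) {
    abort("the first measurement time must be non-negative.")
  }
  invisible(times)
}

#' Interaction coefficient implied by a standardized effect size
#'
#' The treatment-by-time interaction is expressed on the scale of the
#' between-person slope standard deviation:
#' \eqn{\beta_2 = \delta \sqrt{\sigma^2_{u1}}}.
#'
#' @param delta Non-negative standardized effect size. An expected negative
#'   interaction is handled by reversing the direction of the one-sided
#'   hypothesis (see `direction` in [growth_design()]), not by a negative
#'   `delta`.
#' @param var_u1 Non-negative slope variance \eqn{\sigma^2_{u1}}.
#' @return The interaction coefficient \eqn{\beta_2}.
#' @examples
#' beta2_from_effect(0.8, 0.001)  # 0.0253
#' beta2_from_effect(0.4, 0.003)  # 0.0219
#' @export
beta2_from_effect <- function(delta, var_u1) {
  stopifnot(is.numeric(delta), length(delta) == 1L,
            is.numeric(var_u1), length(var_u1) == 1L, var_u1 >= 0)
  if (delta < 0) {
    abort("`delta` must be non-negative; an expected decline is specified with `direction = \"negative\"`, which tests the sign-reflected hypothesis.")
  }
  delta * sqrt(var_u1)
}

check_variance_components <- function(var_e, var_u0, var_u1, cov_u01) {
  stopifnot(is.numeric(var_e), var_e > 0,
            is.numeric(var_u0), var_u0 >= 0,
            is.numeric(var_u1), var_u1 >= 0,
            is.numeric(cov_u01))
  if (cov_u01^2 > var_u0 * var_u1 + 1e-12 * max(var_u0 * var_u1, 1)) {
    abort("`cov_u01^2` must not exceed `var_u0 * var_u1` (random-effect covariance matrix must be positive semi-definite).")
  }
  invisible(NULL)
}

#' Specify a two-arm longitudinal growth trial design
#'
#' Bundles everything the simulation, power estimation and sample size
#' search need: the measurement time grid (optionally log-transformed),
#' the variance components of the two-level growth model, the standardized
#' effect size, and the Bayes-factor evaluation settings. Defaults follow
#' the reference implementation's argument table (time grid 0..4, residual
#' variance 0.02, intercept variance 0.03, slope variance 0.1, zero
#' covariance, effect size 0.8, Bayes factor threshold 3, target power 0.8,
#' 1000 Monte Carlo datasets, minimal prior fraction).
#'
#' The underlying model for subject \eqn{i} at occasion \eqn{j} is
#' \deqn{Y_{ij} = \beta_0 + \beta_1 T_j + \beta_2 C_i T_j
#'   + u_{0i} + u_{1i} T_j + e_{ij},}
#' with \eqn{(u_{0i}, u_{1i}) \sim N(0, \Sigma_u)} and
#' \eqn{e_{ij} \sim N(0, \sigma^2_e)}. The hypotheses evaluated are
#' \eqn{H_0: \beta_2 = 0} and \eqn{H_1: \beta_2 > 0} (or \eqn{\beta_2 < 0}
#' with `direction = "negative"`, which is evaluated by sign reflection).
#'
#' @param t_points Measurement times on the raw scale. Alternatively give
#'   `duration` and `frequency`.
#' @param duration,frequency Optional; build the grid with [time_grid()].
#' @param log_growth Logical; model growth as linear in log-time?
#' @param log_shift Offset inside the log transform (see
#'   [transform_times()]).
#' @param var_e Residual variance \eqn{\sigma^2_e}.
#' @param var_u0 Intercept variance \eqn{\sigma^2_{u0}}.
#' @param var_u1 Slope variance \eqn{\sigma^2_{u1}}.
#' @param cov_u01 Intercept-slope covariance \eqn{\sigma_{u0u1}}.
#' @param eff_size Standardized effect size \eqn{\delta \ge 0}.
#' @param direction `"positive"` tests \eqn{\beta_2 > 0}; `"negative"`
#'   tests \eqn{\beta_2 < 0} via sign reflection.
#' @param beta0 Grand intercept (cancels from the interaction inference).
#' @param beta1 Control-arm mean slope.
#' @param bf_thresh Bayes factor threshold \eqn{BF_{thres} > 0}.
#' @param eta Target power in (0, 1).
#' @param m Number of Monte Carlo datasets per hypothesis per evaluation.
#' @param fraction Multiplier \eqn{J \in \{1, 2, 3\}} of the minimal prior
#'   fraction, \eqn{b = J / N_{eff}}.
#' @param sensitivity Logical; report results for all of
#'   \eqn{J = 1, 2, 3}?
#' @param hypothesis Which true hypotheses to require power for:
#'   `"both"`, `"H0"` or `"H1"`.
#' @param test Comparison hypothesis: `"alt"` (H0 vs H1), `"Hc"`
#'   (complement) or `"Hu"` (unconstrained).
#' @param centered Use the centered time sum of squares in the closed-form
#'   standard error (the default; it is the exact sampling variance for
#'   this design). `FALSE` gives the uncentered textbook variant.
#' @param seed Optional master seed for reproducibility.
#' @return An object of class `growth_design`.
#' @examples
#' d <- growth_design(t_points = 0:4, var_e = 0.0262, var_u0 = 0.0333,
#'                    var_u1 = 0.0030, eff_size = 0.40)
#' d
#' @export
growth_design <- function(t_points = c(0, 1, 2, 3, 4),
                          duration = NULL, frequency = NULL,
                          log_growth = FALSE, log_shift = 0,
                          var_e = 0.02, var_u0 = 0.03, var_u1 = 0.1,
                          cov_u01 = 0,
                          eff_size = 0.8,
                          direction = c("positive", "negative"),
                          beta0 = 0, beta1 = 0,
                          bf_thresh = 3, eta = 0.8, m = 1000,
                          fraction = 1, sensitivity = FALSE,
                          hypothesis = c("both", "H0", "H1"),
                          test = c("alt", "Hc", "Hu"),
                          centered = TRUE,
                          seed = NULL) {
  direction <- match.arg(direction)
  hypothesis <- match.arg(hypothesis)
  test <- match.arg(test)
  if (!is.null(duration) || !is.null(frequency)) {
    if (is.null(duration) || is.null(frequency)) {
      abort("give both `duration` and `frequency`, or neither.")
    }
    t_points <- time_grid(duration, frequency)
  }
  check_times(t_points)
  check_variance_components(var_e, var_u0, var_u1, cov_u01)
  stopifnot(bf_thresh > 0, eta > 0, eta < 1, m >= 1,
            fraction %in% c(1, 2, 3))
  times <- transform_times(t_points, log_growth, log_shift)
  beta2 <- beta2_from_effect(eff_size, var_u1)

  structure(
    list(
      raw_times = as.numeric(t_points),
      times = as.numeric(times),
      log_growth = isTRUE(log_growth),
      log_shift = log_shift,
      var_e = var_e, var_u0 = var_u0, var_u1 = var_u1, cov_u01 = cov_u01,
      eff_size = eff_size, direction = direction,
      beta0 = beta0, beta1 = beta1, beta2 = beta2,
      bf_thresh = bf_thresh, eta = eta, m = as.integer(m),
      fraction = as.integer(fraction), sensitivity = isTRUE(sensitivity),
      hypothesis = hypothesis, test = test,
      centered = isTRUE(centered),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "growth_design"
  )
}

#' @export
print.growth_design <- function(x, ...) {
  cat("<growth_design>\n")
  cat("  occasions : ", paste(signif(x$raw_times, 4), collapse = ", "),
      if (x$log_growth) sprintf(" (log scale, shift %g)", x$log_shift) else "",
      "\n", sep = "")
  cat(sprintf("  variances : e %.4g | u0 %.4g | u1 %.4g | cov %.4g\n",
              x$var_e, x$var_u0, x$var_u1, x$cov_u01))
  cat(sprintf("  effect    : delta %.3g (%s) -> beta2 %.4g | beta1 %.3g\n",
              x$eff_size, x$direction, x$beta2, x$beta1))
  cat(sprintf("  evaluation: BF > %g, eta %.2f, m %d, J %d%s, hyp %s, test %s\n",
              x$bf_thresh, x$eta, x$m, x$fraction,
              if (x$sensitivity) " (+sensitivity)" else "",
              x$hypothesis, x$test))
  invisible(x)
}

# which true hypotheses the power criterion covers
requested_truths <- function(design) {
  switch(design$hypothesis,
         both = c("H0", "H1"),
         H0 = "H0",
         H1 = "H1")
}

requested_fractions <- function(design) {
  if (design$sensitivity) 1:3 else design$fraction
}
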