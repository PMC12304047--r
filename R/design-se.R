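# Design algebra: closed-form standard error of the interaction slope,
# effective sample size and the prior fraction b.

time_sum_squares <- function(times, centered = TRUE) {
  if (centered) sum((times - mean(times))^2) else sum(times^2)
}

#' Closed-form standard error of the interaction coefficient
#'
#' For a balanced two-arm design with \eqn{N} subjects measured at the same
#' occasions, the sampling variance of the estimated treatment-by-time
#' interaction \eqn{\hat\beta_2} is
#' \deqn{\mathrm{Var}(\hat\beta_2) =
#'   \frac{4(\sigma^2_e + \sigma^2_{u1} S)}{N S},}
#' where \eqn{S} is the time sum of squares. With `centered = TRUE`
#' (default) \eqn{S = \sum_j (T_j - \bar T)^2} and the formula is the exact
#' generalized-least-squares variance for the fitted growth model; the
#' uncentered variant \eqn{S = \sum_j T_j^2} appears in some texts and is
#' kept for comparison.
#'
#' @param design A [growth_design()].
#' @param n_subjects Total number of subjects \eqn{N \ge 2} (split evenly
#'   across arms).
#' @param centered Which sum of squares to use; defaults to the design's
#'   setting.
#' @return The standard error (not its square).
#' @examples
#' d <- growth_design(t_points = 0:4, var_e = 0.0262, var_u0 = 0.0333,
#'                    var_u1 = 0.0030, eff_size = 0.40)
#' analytic_se_beta2(d, 704)
#' @export
analytic_se_beta2 <- function(design, n_subjects, centered = design$centered) {
  stopifnot(inherits(design, "growth_design"),
            is.numeric(n_subjects), n_subjects >= 2)
  s <- time_sum_squares(design$times, centered)
  if (s <= 0) {
    abort("the time grid has zero sum of squares; at least two distinct occasions are required.")
  }
  sqrt(4 * (design$var_e + design$var_u1 * s) / (n_subjects * s))
}

# Average marginal variance of an observation across the grid:
# sigma^2_e + sigma^2_u0 + (2/n) sum(T_j) cov + (1/n) sum(T_j^2) sigma^2_u1
average_marginal_variance <- function(design) {
  t <- design$times
  design$var_e + design$var_u0 +
    2 * mean(t) * design$cov_u01 + mean(t^2) * design$var_u1
}

#' Effective sample size of a correlated longitudinal sample
#'
#' Repeated measures within a subject are correlated, so the \eqn{N n}
#' observations carry less information about \eqn{\beta_2} than \eqn{N n}
#' independent ones would. Following the variance-ratio approach, a weight
#' \eqn{w = \mathrm{Var}_{indep}(\hat\beta_2) / \mathrm{Var}(\hat\beta_2)}
#' is computed, where the numerator is the ordinary-least-squares variance
#' under a working model that treats all observations as independent with
#' variance equal to the average marginal variance, and the denominator is
#' the actual variance ([analytic_se_beta2()] squared). Then
#' \eqn{N_{eff} = w N n}, clamped to \eqn{[N, N n]}: a fully informative
#' sample counts every observation, a fully redundant one only every
#' subject. Both variances share the factor \eqn{4/(N S)}, so
#' \eqn{w = \bar\sigma^2 / (\sigma^2_e + \sigma^2_{u1} S)} does not depend
#' on \eqn{N}.
#'
#' @inheritParams analytic_se_beta2
#' @return The effective sample size, a scalar in \eqn{[N, N n]}.
#' @examples
#' d <- growth_design()
#' effective_sample_size(d, 100)
#' @export
effective_sample_size <- function(design, n_subjects,
                                  centered = design$centered) {
  stopifnot(inherits(design, "growth_design"),
            is.numeric(n_subjects), n_subjects >= 2)
  n <- length(design$times)
  s <- time_sum_squares(design$times, centered)
  if (s <= 0) {
    abort("degenerate time grid: zero sum of squares.")
  }
  w <- average_marginal_variance(design) / (design$var_e + design$var_u1 * s)
  min(max(w * n_subjects * n, n_subjects), n_subjects * n)
}

#' Fraction of information used to construct the default prior
#'
#' The default prior of the AAFBF uses a fraction \eqn{b = J / N_{eff}} of
#' the information, where \eqn{J} is the number of independent constraints
#' (here 1) possibly multiplied by 2 or 3 for a less diffuse, more robust
#' prior.
#'
#' @param fraction Multiplier \eqn{J \in \{1, 2, 3\}}.
#' @param n_eff Effective sample size, positive.
#' @return The fraction \eqn{b}.
#' @examples
#' b_fraction(1, 100)  # 0.01
#' @export
b_fraction <- function(fraction, n_eff) {
  stopifnot(fraction %in% c(1, 2, 3), is.numeric(n_eff), n_eff > 0)
  fraction / n_eff
}
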