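# The approximate adjusted fractional Bayes factor (AAFBF) for one
# estimate and squared standard error.
#
# Normal approximations: posterior g_u = N(beta2_hat, se2), default prior
# h_u = N(0, se2 / b), centered at the constraint boundary. Fit and
# complexity are the posterior and prior share in agreement with each
# hypothesis: a density at 0 for the equality constraint, a tail mass for
# the inequality. Everything is computed on the log scale and
# exponentiated at the module boundary.

log_fit_complexity <- function(beta2_hat, se2, b, hypothesis) {
  se <- sqrt(se2)
  switch(hypothesis,
    H0 = c(fit = dnorm(0, beta2_hat, se, log = TRUE),
           comp = dnorm(0, 0, se / sqrt(b), log = TRUE)),
    H1 = c(fit = pnorm(beta2_hat / se, log.p = TRUE),
           comp = log(0.5)),
    Hc = c(fit = pnorm(beta2_hat / se, lower.tail = FALSE, log.p = TRUE),
           comp = log(0.5)),
    abort("unknown hypothesis"))
}

#' Fit and complexity of a hypothesis about the interaction
#'
#' Fit is the share of the (approximate normal) posterior in agreement
#' with the hypothesis; complexity is the same share under the default
#' fractional prior \eqn{N(0, \sigma^2_{\hat\beta_2}/b)}. For the equality
#' hypothesis both are densities at zero; for the one-sided hypothesis
#' \eqn{\beta_2 > 0} the complexity is exactly 0.5 because the prior is
#' centered at the boundary, and the fit is the upper-tail posterior mass.
#'
#' @param beta2_hat Estimate of the interaction coefficient.
#' @param se2 Its squared standard error, positive.
#' @param b Prior fraction, \eqn{0 < b \le 1}.
#' @param hypothesis `"H0"` (\eqn{\beta_2 = 0}), `"H1"`
#'   (\eqn{\beta_2 > 0}) or `"Hc"` (\eqn{\beta_2 \le 0}).
#' @return Named numeric vector `c(fit, complexity)`.
#' @examples
#' fit_and_complexity(0.5, 0.1, 0.01, "H0")  # fit 0.361, complexity 0.126
#' @export
fit_and_complexity <- function(beta2_hat, se2, b,
                               hypothesis = c("H0", "H1", "Hc")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(is.numeric(beta2_hat), is.numeric(se2), se2 > 0)
  if (!is.numeric(b) || b <= 0 || b > 1) {
    abort("`b` must lie in (0, 1].")
  }
  lg <- log_fit_complexity(beta2_hat, se2, b, hypothesis)
  c(fit = exp(lg[["fit"]]), complexity = exp(lg[["comp"]]))
}

# Vectorized log Bayes factors used by the power engine; direction must
# already be applied (estimates sign-flipped for a negative-direction
# hypothesis).
log_bf_components <- function(beta2_hat, se2, b) {
  se <- sqrt(se2)
  z <- beta2_hat / se
  log_fit0 <- dnorm(0, beta2_hat, se, log = TRUE)
  log_comp0 <- dnorm(0, 0, se / sqrt(b), log = TRUE)
  log_fit1 <- pnorm(z, log.p = TRUE)
  log_fitc <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  list(bf_0u = log_fit0 - log_comp0,
       bf_1u = log_fit1 - log(0.5),
       bf_1c = log_fit1 - log_fitc)
}

# log BF favoring `truth` under the requested comparison.
log_bf_for_truth <- function(beta2_hat, se2, b, truth, test) {
  lb <- log_bf_components(beta2_hat, se2, b)
  if (truth == "H1") {
    switch(test,
           alt = lb$bf_1u - lb$bf_0u,  # BF_10
           Hc = lb$bf_1c,
           Hu = lb$bf_1u)
  } else {
    switch(test,
           alt = lb$bf_0u - lb$bf_1u,  # BF_01
           # the complement of an equality hypothesis is the unconstrained
           # hypothesis up to a null set, so H0 is compared against Hu
           Hc = lb$bf_0u,
           Hu = lb$bf_0u)
  }
}

#' Approximate adjusted fractional Bayes factor
#'
#' Computes all Bayes factors derivable from one interaction estimate, its
#' squared standard error and the prior fraction `b`:
#' \eqn{BF_{0u} = fit_0 / comp_0} (a Savage-Dickey density ratio),
#' \eqn{BF_{1u} = fit_1 / comp_1}, their ratio \eqn{BF_{01}} (and
#' \eqn{BF_{10}}), and the complement comparison
#' \eqn{BF_{1c} = fit_1 / (1 - fit_1)}. For a hypothesis about a decline
#' (`direction = "negative"`) the estimate is sign-reflected first, which
#' is equivalent to testing \eqn{\beta_2 < 0}.
#'
#' @inheritParams fit_and_complexity
#' @param direction `"positive"` (test \eqn{\beta_2 > 0}) or
#'   `"negative"` (test \eqn{\beta_2 < 0}).
#' @return An object of class `aafbf`; `tidy()` turns it into a tibble.
#' @examples
#' bf <- aafbf(0.5, 0.1, b = 0.01)
#' bf
#' tidy(bf)
#' @export
aafbf <- function(beta2_hat, se2, b, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(beta2_hat), length(beta2_hat) == 1L,
            is.numeric(se2), length(se2) == 1L, se2 > 0)
  if (!is.numeric(b) || length(b) != 1L || b <= 0 || b > 1) {
    abort("`b` must lie in (0, 1].")
  }
  est <- if (direction == "negative") -beta2_hat else beta2_hat
  lg0 <- log_fit_complexity(est, se2, b, "H0")
  lg1 <- log_fit_complexity(est, se2, b, "H1")
  lgc <- log_fit_complexity(est, se2, b, "Hc")
  lb <- log_bf_components(est, se2, b)
  structure(
    list(estimate = beta2_hat, se2 = se2, b = b, direction = direction,
         prior_mean = 0, prior_var = se2 / b,
         post_mean = beta2_hat, post_var = se2,
         fit0 = exp(lg0[["fit"]]), comp0 = exp(lg0[["comp"]]),
         fit1 = exp(lg1[["fit"]]), comp1 = 0.5,
         fitc = exp(lgc[["fit"]]), compc = 0.5,
         bf_0u = exp(lb$bf_0u), bf_1u = exp(lb$bf_1u),
         bf_01 = exp(lb$bf_0u - lb$bf_1u),
         bf_10 = exp(lb$bf_1u - lb$bf_0u),
         bf_1c = exp(lb$bf_1c),
         bf_0c = exp(lb$bf_0u)),
    class = "aafbf")
}

#' @export
print.aafbf <- function(x, ...) {
  cat(sprintf("<aafbf: estimate %.4g, se2 %.4g, b %.4g%s>\n",
              x$estimate, x$se2, x$b,
              if (x$direction == "negative") ", negative direction" else ""))
  cat(sprintf("  fit0 %.4g comp0 %.4g | fit1 %.4g comp1 %.2g\n",
              x$fit0, x$comp0, x$fit1, x$comp1))
  cat(sprintf("  BF_0u %.4g  BF_1u %.4g  BF_01 %.4g  BF_1c %.4g\n",
              x$bf_0u, x$bf_1u, x$bf_01, x$bf_1c))
  invisible(x)
}

#' Tidy an AAFBF result
#'
#' @param x An `aafbf` object.
#' @param ... Unused.
#' @return A tibble with one row per Bayes factor.
#' @export
tidy.aafbf <- function(x, ...) {
  tibble(
    comparison = c("H0 vs Hu", "H1 vs Hu", "H0 vs H1", "H1 vs H0",
                   "H1 vs Hc", "H0 vs complement (Hu)"),
    bayes_factor = c(x$bf_0u, x$bf_1u, x$bf_01, x$bf_10, x$bf_1c, x$bf_0c),
    b = x$b)
}
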