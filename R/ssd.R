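# Binary search for the minimal number of subjects meeting the Bayesian
# power criterion, with an optional sensitivity analysis over the prior
# fraction multiplier J.

#' Find the minimal sample size meeting the power criterion
#'
#' Halves the interval `[n_min, n_max]` on the power criterion: the power
#' at the midpoint is estimated (Monte Carlo, `m` datasets per requested
#' hypothesis), the midpoint replaces the upper bound when the criterion
#' \eqn{\eta \ge} target is met under every requested hypothesis and the
#' lower bound otherwise, until the bounds are adjacent; the upper bound is
#' returned with its \eqn{\eta_0, \eta_1}. Fitted estimates at a given
#' sample size are shared across fractions (the posterior does not depend
#' on \eqn{b}) and across iterations of the different fraction searches.
#' Each evaluated sample size uses fresh datasets with deterministic child
#' seeds, so reruns with the same master seed are identical.
#'
#' Monte Carlo noise can make estimated power locally non-monotone; the
#' search tolerates this silently (binary search assumes a monotone power
#' curve) but the full trace is returned and a warning is raised when a
#' larger evaluated sample size showed lower power.
#'
#' @param design A [growth_design()].
#' @param n_min,n_max Search bounds (defaults 30 and 1000, both at least
#'   4).
#' @param fractions Fraction multipliers to search over; defaults to the
#'   design's fraction, or `1:3` when the design requests a sensitivity
#'   analysis.
#' @param m Monte Carlo datasets per hypothesis per evaluation.
#' @param seed Master seed.
#' @param power_fn Optional replacement power function
#'   `function(design, n, fraction)` returning
#'   `c(eta0 = , eta1 = )` (NA for hypotheses not requested); used to run
#'   the search on the deterministic oracle.
#' @return An `ssd_result`: the minimal sample size per fraction with its
#'   power, the full search trace, and any boundary notes.
#' @examples
#' d <- growth_design(eff_size = 0.8, var_u1 = 0.003, var_e = 0.0262,
#'                    var_u0 = 0.0333, m = 40, eta = 0.8)
#' find_sample_size(d, n_min = 10, n_max = 200, seed = 1)
#' @export
find_sample_size <- function(design, n_min = 30, n_max = 1000,
                             fractions = requested_fractions(design),
                             m = design$m, seed = design$seed,
                             power_fn = NULL) {
  stopifnot(inherits(design, "growth_design"),
            n_min >= 4, n_max > n_min)
  if (is.null(seed)) seed <- 0L
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  truths <- requested_truths(design)

  batches <- new.env(parent = emptyenv())
  get_batch <- function(truth, n) {
    key <- paste0(truth, ":", n)
    if (is.null(batches[[key]])) {
      batches[[key]] <- fit_batch(design, n, truth, m, seed)
    }
    batches[[key]]
  }
  evaluate <- function(n, j) {
    if (!is.null(power_fn)) {
      p <- power_fn(design, n, j)
      eta0 <- unname(p["eta0"]); eta1 <- unname(p["eta1"])
    } else {
      eta0 <- if ("H0" %in% truths) {
        power_from_batch(get_batch("H0", n), design, n, j, "H0")
      } else NA_real_
      eta1 <- if ("H1" %in% truths) {
        power_from_batch(get_batch("H1", n), design, n, j, "H1")
      } else NA_real_
    }
    relevant <- c(if ("H0" %in% truths) eta0, if ("H1" %in% truths) eta1)
    list(eta0 = eta0, eta1 = eta1, met = all(relevant >= design$eta))
  }

  trace <- list()
  notes <- character()
  per_b <- purrr::map_dfr(fractions, function(j) {
    lo <- n_min; hi <- n_max
    hi_eval <- NULL
    it <- 0L
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      p <- evaluate(mid, j)
      it <- it + 1L
      trace[[length(trace) + 1L]] <<- tibble(
        fraction = as.integer(j), iteration = it, n = mid,
        eta0 = p$eta0, eta1 = p$eta1, met = p$met,
        decision = if (p$met) "shrink upper" else "raise lower")
      if (p$met) { hi <- mid; hi_eval <- p } else lo <- mid
    }
    if (is.null(hi_eval) || hi != trace[[length(trace)]]$n) {
      # upper bound inherited, not yet evaluated at the returned size
      if (is.null(hi_eval)) {
        p <- evaluate(hi, j)
        it <- it + 1L
        trace[[length(trace) + 1L]] <<- tibble(
          fraction = as.integer(j), iteration = it, n = hi,
          eta0 = p$eta0, eta1 = p$eta1, met = p$met,
          decision = "bound check")
        if (!p$met) {
          abort(sprintf(
            "the power criterion is not met at n_max = %d (eta0 = %s, eta1 = %s < eta = %g); increase n_max, the duration or frequency of observation, or relax the criterion.",
            hi, format(p$eta0, digits = 3), format(p$eta1, digits = 3),
            design$eta), class = "growthssd_unattainable")
        }
        hi_eval <- p
      }
    }
    result_n <- hi; result <- hi_eval
    if (hi == n_min + 1L) {
      p0 <- evaluate(n_min, j)
      it <- it + 1L
      trace[[length(trace) + 1L]] <<- tibble(
        fraction = as.integer(j), iteration = it, n = n_min,
        eta0 = p0$eta0, eta1 = p0$eta1, met = p0$met,
        decision = "bound check")
      if (p0$met) {
        result_n <- n_min; result <- p0
        notes <<- c(notes, sprintf(
          "fraction %d: the power criterion is already met at n_min = %d; the true minimal sample size may be smaller.",
          j, n_min))
      }
    }
    tibble(fraction = as.integer(j), n = result_n,
           eta0 = result$eta0, eta1 = result$eta1)
  })

  trace <- dplyr::bind_rows(trace)
  # audit monotonicity within each fraction's evaluations
  viol <- trace |>
    dplyr::mutate(relevant = pmin(
      ifelse(is.na(.data$eta0), Inf, .data$eta0),
      ifelse(is.na(.data$eta1), Inf, .data$eta1))) |>
    dplyr::group_by(.data$fraction) |>
    dplyr::arrange(.data$n, .by_group = TRUE) |>
    dplyr::summarise(bad = any(diff(.data$relevant) < 0), .groups = "drop")
  if (any(viol$bad)) {
    warn("estimated power was not monotone across evaluated sample sizes (Monte Carlo noise); inspect the search trace.")
  }
  for (msg in notes) warn(msg)

  structure(
    list(per_b = per_b, trace = trace, n_min = n_min, n_max = n_max,
         design = design, seed = seed, m = m, notes = notes),
    class = "ssd_result")
}

#' Sensitivity of the sample size to the prior fraction
#'
#' Runs [find_sample_size()] for \eqn{J = 1, 2, 3}, sharing fitted
#' estimates wherever the searches evaluate the same sample size. A larger
#' \eqn{J} concentrates the prior, which favors the equality hypothesis
#' less, so for equality-inclusive tests the required sample size is
#' non-increasing in \eqn{J}; for inequality-only comparisons the Bayes
#' factor does not depend on \eqn{b} at all and the three results
#' coincide.
#'
#' @inheritParams find_sample_size
#' @return An `ssd_result` with one row per fraction.
#' @export
sensitivity_analysis <- function(design, n_min = 30, n_max = 1000,
                                 m = design$m, seed = design$seed,
                                 power_fn = NULL) {
  find_sample_size(design, n_min, n_max, fractions = 1:3, m = m,
                   seed = seed, power_fn = power_fn)
}

#' @export
print.ssd_result <- function(x, ...) {
  cat("<ssd_result>\n")
  cat(sprintf("  search bounds [%d, %d], m = %d per hypothesis, eta target %.2f\n",
              x$n_min, x$n_max, x$m, x$design$eta))
  for (i in seq_len(nrow(x$per_b))) {
    r <- x$per_b[i, ]
    cat(sprintf("  J = %d: N = %d (eta0 %s, eta1 %s)\n", r$fraction, r$n,
                format(r$eta0, digits = 3), format(r$eta1, digits = 3)))
  }
  if (length(x$notes)) cat("  note:", x$notes[1L], "\n")
  invisible(x)
}

#' @export
tidy.ssd_result <- function(x, ...) as_tibble(x$per_b)

#' @export
glance.ssd_result <- function(x, ...) {
  first <- x$per_b[1L, ]
  tibble(n = first$n, eta0 = first$eta0, eta1 = first$eta1,
         fraction = first$fraction,
         n_evaluations = nrow(x$trace),
         n_min = x$n_min, n_max = x$n_max)
}

#' @export
autoplot.ssd_result <- function(object, ...) {
  df <- object$trace |>
    tidyr::pivot_longer(c("eta0", "eta1"), names_to = "hypothesis",
                        values_to = "power") |>
    dplyr::filter(!is.na(.data$power)) |>
    dplyr::mutate(hypothesis = ifelse(.data$hypothesis == "eta0",
                                      "H0", "H1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$power,
                                   colour = .data$hypothesis)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$design$eta,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~ fraction, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "evaluated sample size N", y = "estimated power")
}
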