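# Trial simulation from the two-level growth model.

#' Deterministic treatment allocation
#'
#' Splits `n_subjects` across the two arms as evenly as possible:
#' `floor(n_subjects / 2)` treated subjects, the remainder (including the
#' extra subject when `n_subjects` is odd) in the control arm. The
#' allocation is deterministic; randomization plays no role in the power of
#' a balanced two-arm comparison.
#'
#' @param n_subjects Number of subjects, at least 2.
#' @return Integer vector of 0 (control) and 1 (treatment), sorted.
#' @examples
#' allocate_conditions(5)
#' @export
allocate_conditions <- function(n_subjects) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 2) {
    abort("`n_subjects` must be a single number >= 2.")
  }
  n_subjects <- as.integer(n_subjects)
  n1 <- n_subjects %/% 2L
  c(rep(0L, n_subjects - n1), rep(1L, n1))
}

# Deterministic child seed from (master, truth, N, k, attempt).
# Mixing is done in double precision (exact below 2^53) modulo the Mersenne
# prime 2^31 - 1, so any single dataset is reproducible in isolation and
# parallel execution order cannot matter.
child_seed <- function(master, truth, n_subjects, k, attempt = 0L) {
  m <- 2147483647
  h <- if (identical(truth, "H1")) 2 else 1
  x <- (abs(as.numeric(master)) %% m)
  for (v in c(h, as.numeric(n_subjects), as.numeric(k), as.numeric(attempt))) {
    x <- (x * 1048573 + v + 1) %% m
  }
  as.integer(x) + 1L
}

# PSD factor of the random-effect covariance; tolerates rank deficiency
# (e.g. var_u1 = 0, in which case the covariance must be 0 too).
sigma_u_factor <- function(design) {
  su <- matrix(c(design$var_u0, design$cov_u01,
                 design$cov_u01, design$var_u1), 2L, 2L)
  e <- eigen(su, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), 2L)
}

# Core generator: returns the N x n outcome matrix (control rows first)
# plus the condition vector. Draw order (random effects, then residuals) is
# fixed so that the tibble and matrix paths agree exactly.
simulate_outcome_matrix <- function(design, n_subjects, truth = c("H1", "H0"),
                                    seed = NULL) {
  truth <- match.arg(truth)
  cond <- allocate_conditions(n_subjects)
  n <- length(design$times)
  if (!is.null(seed)) set.seed(seed)
  A <- sigma_u_factor(design)
  u <- matrix(rnorm(2L * n_subjects), ncol = 2L) %*% t(A)
  e <- matrix(rnorm(n_subjects * n, sd = sqrt(design$var_e)),
              nrow = n_subjects, ncol = n)
  # the stored coefficient is a magnitude; the direction flag carries the
  # sign of the hypothesized (and generated) effect
  beta2 <- if (truth == "H1") {
    if (design$direction == "negative") -design$beta2 else design$beta2
  } else 0
  slope <- design$beta1 + beta2 * cond + u[, 2L]
  y <- design$beta0 + u[, 1L] + tcrossprod(slope, design$times) + e
  list(y = y, condition = cond)
}

#' Simulate one trial dataset
#'
#' Generates a complete balanced trial from the combined two-level growth
#' model
#' \eqn{Y_{ij} = \beta_0 + \beta_1 T_j + \beta_2 C_i T_j + u_{0i} +
#' u_{1i} T_j + e_{ij}}. Under `truth = "H0"` the generating interaction is
#' zero; under `"H1"` it is \eqn{\delta\sqrt{\sigma^2_{u1}}}. Time is the
#' transformed grid (log scale when the design uses log-linear growth), so
#' a log-growth trial is exactly a linear-growth trial on the transformed
#' axis.
#'
#' @param design A [growth_design()].
#' @param n_subjects Total number of subjects.
#' @param truth Generating hypothesis, `"H1"` (default) or `"H0"`.
#' @param seed Optional integer seed for this dataset.
#' @return A tibble with columns `subject`, `condition`, `time`, `y` and
#'   `n_subjects * n` rows.
#' @examples
#' d <- growth_design(eff_size = 0.4, var_u1 = 0.003)
#' sim <- simulate_trial(d, 10, seed = 1)
#' head(sim)
#' @export
simulate_trial <- function(design, n_subjects, truth = c("H1", "H0"),
                           seed = NULL) {
  stopifnot(inherits(design, "growth_design"))
  truth <- match.arg(truth)
  sim <- simulate_outcome_matrix(design, n_subjects, truth, seed)
  n <- length(design$times)
  tibble(
    subject = rep(seq_len(n_subjects), each = n),
    condition = rep(sim$condition, each = n),
    time = rep(design$times, times = n_subjects),
    y = as.vector(t(sim$y))
  )
}

#' Write or read a simulated trial as CSV
#'
#' Long-format dump with header `subject,condition,time,y`; time is on the
#' transformed scale used for fitting.
#'
#' @param data A trial tibble from [simulate_trial()].
#' @param path File path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns the tibble.
#' @export
write_trial_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  as_tibble(utils::read.csv(path))
}
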