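# Model estimation: a fast profiled-likelihood fitter for balanced designs
# (the default) and an lme4 engine kept as an independent cross-check.
#
# The fitted fixed-effect structure is intercept, condition, time and
# condition:time; the last coefficient is the treatment-by-time interaction
# beta2, the only parameter the Bayes factor consumes. Random structure:
# correlated subject-level intercepts and time slopes.

# Constant (theta-independent) pieces for a given grid and arm split,
# flattened for the compiled criterion.
fit_constants <- function(times, n0, n1, reml = TRUE) {
  n <- length(times)
  Z <- cbind(1, times)
  X0 <- cbind(1, 0, times, 0)
  X1 <- cbind(1, 1, times, times)
  cst <- c(n, n0, n1, as.numeric(reml),
           as.vector(crossprod(Z)),
           as.vector(crossprod(X0)),
           as.vector(crossprod(X1)),
           as.vector(crossprod(X0, Z)),
           as.vector(crossprod(X1, Z)))
  list(cst = cst, Z = Z, M = crossprod(Z), n = n, n0 = n0, n1 = n1)
}

# Sufficient statistics of one dataset given as an outcome matrix with the
# control arm in the first n0 rows.
fit_stats <- function(y, consts) {
  n0 <- consts$n0
  y0 <- y[seq_len(n0), , drop = FALSE]
  y1 <- y[-seq_len(n0), , drop = FALSE]
  yb0 <- colMeans(y0)
  yb1 <- colMeans(y1)
  Sw <- crossprod(y) - n0 * tcrossprod(yb0) - consts$n1 * tcrossprod(yb1)
  Z <- consts$Z
  t <- Z[, 2L]
  v0 <- c(sum(yb0), 0, sum(t * yb0), 0)
  v1 <- c(sum(yb1), sum(yb1), sum(t * yb1), sum(t * yb1))
  c(crossprod(Z, yb0), crossprod(Z, yb1), v0, v1,
    sum(yb0^2), sum(yb1^2), sum(diag(Sw)), crossprod(Z, Sw %*% Z))
}

# Method-of-moments starting values for the log-Cholesky parameters of
# G = Sigma_u / sigma^2, from per-subject OLS coefficient dispersion.
fit_start <- function(dat, consts) {
  n <- consts$n
  N <- consts$n0 + consts$n1
  Minv <- solve(consts$M)
  SZZ <- matrix(dat[16:19], 2L, 2L)
  trSw <- dat[15L]
  rss <- trSw - sum(diag(Minv %*% SZZ))
  s2 <- if (n > 2L && rss > 0) rss / ((N - 2) * (n - 2)) else trSw / ((N - 2) * n)
  s2 <- max(s2, 1e-12)
  Sb <- Minv %*% SZZ %*% Minv / (N - 2)
  G0 <- (Sb - s2 * Minv) / s2
  e <- eigen((G0 + t(G0)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  G0 <- e$vectors %*% diag(vals, 2L) %*% t(e$vectors)
  L <- t(chol(G0))
  c(log(L[1L, 1L]), L[2L, 1L], log(L[2L, 2L]))
}

fit_balanced_core <- function(dat, consts, reml = TRUE) {
  cst <- consts$cst
  cst[4L] <- as.numeric(reml)
  start <- tryCatch(fit_start(dat, consts), error = function(e) c(-2, 0, -2))
  opt <- optim(start, crit_balanced, dat = dat, cst = cst,
               method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 1000L))
  res <- extract_balanced(opt$par, dat, cst)
  if (!isTRUE(res$ok) || opt$value >= 1e9) {
    return(list(ok = FALSE, converged = FALSE, singular = NA))
  }
  su <- res$Sigma_u
  singular <- min(diag(su)) < 1e-10 * max(res$sigma2_e, diag(su), 1e-300) ||
    abs(su[1L, 2L]) > 0.9999 * sqrt(prod(diag(su))) + 1e-300
  list(ok = TRUE, converged = opt$convergence == 0L,
       singular = singular, beta = as.numeric(res$beta),
       se2_beta2 = res$se2_beta2, sigma2_e = res$sigma2_e,
       Sigma_u = su, vcov_beta = res$vcov_beta,
       criterion = opt$value)
}

new_growth_fit <- function(core, method, engine, n_subjects, n_occasions) {
  beta <- setNames(core$beta,
                   c("(Intercept)", "condition", "time", "condition:time"))
  structure(
    list(beta2_hat = beta[["condition:time"]],
         se2_beta2 = core$se2_beta2,
         fixed_effects = beta,
         vcov_beta = core$vcov_beta,
         sigma2_e = core$sigma2_e,
         Sigma_u = core$Sigma_u,
         converged = core$converged,
         singular = core$singular,
         method = method, engine = engine,
         n_subjects = n_subjects, n_occasions = n_occasions),
    class = "growth_fit")
}

# Reshape a long trial tibble into the matrix form used internally.
# Requires a balanced design: every subject measured at the same times.
trial_to_matrix <- function(data) {
  need <- c("subject", "condition", "time", "y")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns subject, condition, time and y.")
  }
  data <- dplyr::arrange(data, .data$condition, .data$subject, .data$time)
  times <- sort(unique(data$time))
  n <- length(times)
  counts <- table(data$subject)
  if (length(unique(as.integer(counts))) != 1L ||
      as.integer(counts[1L]) != n || nrow(data) %% n != 0L) {
    abort("unbalanced data: every subject must be measured on the same time grid.")
  }
  N <- nrow(data) / n
  y <- matrix(data$y, nrow = N, ncol = n, byrow = TRUE)
  cond <- data$condition[seq(1L, nrow(data), by = n)]
  if (any(!cond %in% c(0, 1))) abort("`condition` must be coded 0/1.")
  list(y = y, condition = as.integer(cond), times = times)
}

#' Fit the two-level growth model to one trial dataset
#'
#' Estimates fixed effects (intercept, condition, time, condition-by-time)
#' with correlated random intercepts and time slopes per subject, and
#' returns the interaction estimate \eqn{\hat\beta_2} with its squared
#' standard error. The default engine exploits the balanced design: the
#' likelihood depends on the data only through per-arm means and the pooled
#' within-arm cross-product matrix, and the residual variance is profiled
#' out, leaving a three-parameter optimization over the scaled
#' random-effect covariance. The `"lmer"` engine fits the identical model
#' with [lme4::lmer()] and is retained as an independent cross-check.
#'
#' @param data Long-format tibble with columns `subject`, `condition`
#'   (0/1), `time`, `y`; every subject must be measured at the same times.
#' @param method `"REML"` (default) or `"ML"`.
#' @param engine `"balanced"` (default) or `"lmer"`.
#' @return A `growth_fit` object; see [tidy.growth_fit()] and
#'   [glance.growth_fit()].
#' @examples
#' d <- growth_design(eff_size = 0.4, var_u1 = 0.003)
#' fit <- fit_growth_model(simulate_trial(d, 60, seed = 1))
#' glance(fit)
#' @export
fit_growth_model <- function(data, method = c("REML", "ML"),
                             engine = c("balanced", "lmer")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  parts <- trial_to_matrix(data)
  N <- nrow(parts$y)
  n0 <- sum(parts$condition == 0L)
  if (n0 < 2L || N - n0 < 2L) {
    abort("at least two subjects per arm are required.")
  }
  if (engine == "lmer") {
    return(fit_growth_lmer(data, method))
  }
  consts <- fit_constants(parts$times, n0, N - n0, method == "REML")
  core <- fit_balanced_core(fit_stats(parts$y, consts), consts,
                            method == "REML")
  if (!core$ok) {
    abort("model fit failed (degenerate dataset).")
  }
  new_growth_fit(core, method, "balanced", N, length(parts$times))
}

fit_growth_lmer <- function(data, method) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    abort("engine \"lmer\" requires the lme4 package.")
  }
  fml <- y ~ condition * time + (time | subject)
  fit <- lme4::lmer(fml, data = data, REML = method == "REML",
                    control = lme4::lmerControl(calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  su <- matrix(0, 2L, 2L)
  su[1L, 1L] <- vc$vcov[vc$grp == "subject" & vc$var1 == "(Intercept)" &
                          is.na(vc$var2)]
  su[2L, 2L] <- vc$vcov[vc$grp == "subject" & vc$var1 == "time" &
                          is.na(vc$var2)]
  su[1L, 2L] <- su[2L, 1L] <-
    vc$vcov[vc$grp == "subject" & !is.na(vc$var2)]
  core <- list(
    beta = as.numeric(fe[c("(Intercept)", "condition", "time",
                           "condition:time")]),
    se2_beta2 = as.numeric(diag(as.matrix(stats::vcov(fit)))["condition:time"]),
    vcov_beta = as.matrix(stats::vcov(fit)),
    sigma2_e = vc$vcov[vc$grp == "Residual"],
    Sigma_u = su,
    converged = length(fit@optinfo$conv$lme4) == 0L,
    singular = lme4::isSingular(fit))
  new_growth_fit(core, method, "lmer",
                 length(unique(data$subject)), length(unique(data$time)))
}

#' Generalized least squares interaction estimate with known components
#'
#' Treats the design's variance components as known, so the fixed effects
#' are a single weighted least-squares solve and the standard error is
#' exact. Used as a fast oracle in tests; with all between-subject
#' variances zero it reduces to ordinary least squares.
#'
#' @inheritParams fit_growth_model
#' @param design A [growth_design()] supplying \eqn{\sigma^2_e} and
#'   \eqn{\Sigma_u}.
#' @return A `growth_fit` object (always converged, never singular).
#' @export
gls_beta2 <- function(data, design) {
  stopifnot(inherits(design, "growth_design"))
  parts <- trial_to_matrix(data)
  N <- nrow(parts$y)
  n0 <- sum(parts$condition == 0L)
  consts <- fit_constants(parts$times, n0, N - n0, TRUE)
  dat <- fit_stats(parts$y, consts)
  G <- matrix(c(design$var_u0, design$cov_u01,
                design$cov_u01, design$var_u1), 2L, 2L) / design$var_e
  # same Woodbury assembly as the compiled criterion, at fixed G
  K <- diag(2L) + consts$M %*% G
  W <- G %*% solve(K)
  W <- (W + t(W)) / 2
  Z <- consts$Z
  t <- Z[, 2L]
  X0 <- cbind(1, 0, t, 0); X1 <- cbind(1, 1, t, t)
  C0 <- crossprod(X0, Z); C1 <- crossprod(X1, Z)
  w0 <- dat[1:2]; w1 <- dat[3:4]; v0 <- dat[5:8]; v1 <- dat[9:12]
  H <- n0 * (crossprod(X0) - C0 %*% W %*% t(C0)) +
    (N - n0) * (crossprod(X1) - C1 %*% W %*% t(C1))
  rhs <- n0 * (v0 - C0 %*% (W %*% w0)) + (N - n0) * (v1 - C1 %*% (W %*% w1))
  beta <- solve(H, rhs)
  core <- list(beta = as.numeric(beta),
               se2_beta2 = design$var_e * solve(H)[4L, 4L],
               vcov_beta = design$var_e * solve(H),
               sigma2_e = design$var_e,
               Sigma_u = G * design$var_e,
               converged = TRUE, singular = FALSE)
  new_growth_fit(core, "GLS", "gls", N, length(parts$times))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit: %s/%s, N = %d, n = %d>\n",
              x$method, x$engine, x$n_subjects, x$n_occasions))
  cat(sprintf("  beta2_hat = %.5g (se %.5g)%s%s\n",
              x$beta2_hat, sqrt(x$se2_beta2),
              if (!x$converged) " [not converged]" else "",
              if (isTRUE(x$singular)) " [singular]" else ""))
  invisible(x)
}

#' Tidy a fitted growth model
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = names(x$fixed_effects),
         estimate = as.numeric(x$fixed_effects),
         std.error = sqrt(pmax(diag(x$vcov_beta), 0)))
}

#' One-row summary of a fitted growth model
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with the interaction estimate, its squared standard
#'   error, variance components and convergence flags.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(beta2_hat = x$beta2_hat, se2_beta2 = x$se2_beta2,
         sigma2_e = x$sigma2_e,
         var_u0 = x$Sigma_u[1L, 1L], var_u1 = x$Sigma_u[2L, 2L],
         cov_u01 = x$Sigma_u[1L, 2L],
         converged = x$converged, singular = x$singular,
         method = x$method, engine = x$engine)
}
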