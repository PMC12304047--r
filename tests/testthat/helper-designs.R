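# Shared fixtures, built in code.

# Replication design of the first worked trial: linear growth, yearly
# measurements over four years, both hypotheses tested against each other.
example1_design <- function(m = 1000, eta = 0.8, bf_thresh = 3,
                            hypothesis = "both", test = "alt",
                            eff_size = 0.40, ...) {
  growth_design(t_points = 0:4, var_e = 0.0262, var_u0 = 0.0333,
                var_u1 = 0.0030, cov_u01 = 0, eff_size = eff_size,
                beta1 = 0, bf_thresh = bf_thresh, eta = eta, m = m,
                hypothesis = hypothesis, test = test, ...)
}

# Parameter set behind the duration/frequency power tables (slope variance
# read as 0.001, consistent with the printed interaction 0.8*sqrt(0.001)).
tables_design <- function(t_points, m = 1000, ...) {
  growth_design(t_points = t_points, var_e = 0.02, var_u0 = 0.0333,
                var_u1 = 0.001, cov_u01 = 0, eff_size = 0.8,
                beta1 = 0, bf_thresh = 3, m = m, ...)
}

# Oracle-backed power function for search tests (no simulation).
oracle_power_fn <- function(design, n, fraction) {
  truths <- growthssd:::requested_truths(design)
  c(eta0 = if ("H0" %in% truths)
      analytic_power(design, n, "H0", fraction) else NA_real_,
    eta1 = if ("H1" %in% truths)
      analytic_power(design, n, "H1", fraction) else NA_real_)
}
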