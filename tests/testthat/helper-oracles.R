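# Shared fixtures and independent oracles for the test suite.

# A hand-picked parameter set with the physiological population ordering
# (P ~ 1e5, S in (1e4, P), P < TDl < TDm).
fixture_params <- function() {
  normal_parameter_set(
    p0_max = 0.7, p1_max = 0.45, q1_max = 0.15,
    eta1_max = 0.02, eta2_max = 0.6, d_l = 0.003, d_m = 0.005,
    gamma1 = (2 * 0.7 - 1) / 1e5, gamma2 = 0.1, gamma3 = 1e-3,
    gamma4 = 0.02, gamma5 = 20)
}

# Full Hill-form RHS for an arbitrary regulation scheme, used as the
# ODE-integration oracle for the design-space screen. theta is in the
# design-space layout (see hemopoiesis:::THETA_NAMES), natural scale.
hill_rhs_scheme <- function(code, theta, y) {
  reg <- function(q, base) {
    cd <- code[q]
    if (cd == 0) return(theta[q])
    src <- y[(cd - 1) %/% 2 + 1]
    g <- theta[7 + q] * src
    if ((cd - 1) %% 2 == 0) theta[q] / (1 + g) else theta[q] * g / (1 + g)
  }
  p0 <- reg(1); p1 <- reg(2); q1 <- reg(3); e1 <- reg(4); e2 <- reg(5)
  c((2 * p0 - 1) * e1 * y[1],
    2 * (1 - p0) * e1 * y[1] + (2 * p1 - 1) * e2 * y[2],
    2 * q1 * e2 * y[2] - theta[6] * y[3],
    2 * (1 - p1 - q1) * e2 * y[2] - theta[7] * y[4])
}

# Plain RK4 integrator (independent of the package's compiled solver).
rk4 <- function(rhs, y0, t_end, dt) {
  y <- y0
  n <- ceiling(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- rhs(y); k2 <- rhs(y + dt / 2 * k1)
    k3 <- rhs(y + dt / 2 * k2); k4 <- rhs(y + dt * k3)
    y <- pmax(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    if (any(!is.finite(y))) return(rep(NA_real_, length(y0)))
  }
  y
}

# Deterministic synthetic transcript series.
fixture_series <- function(values, months = seq_along(values) - 1) {
  structure(data.frame(patient_id = 1L, month = months,
                       bcr_abl_pct = values),
            class = c("transcript_series", "data.frame"))
}

# Small deterministic cohort shared across test files (memoized).
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_grid_search(2500, seed = 7,
                                ranges = enriched_sampling_ranges())
    cache
  }
})
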