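#' Effective (feedback-regulated) rates
#'
#' Evaluates the five regulated quantities at given regulator levels.
#' Regulators are the *total* populations (normal plus leukemic when a
#' dual system is simulated). The differentiation-therapy strength
#' `delta` enters the self-renewal denominator only:
#' `p0 = p0_max / (1 + gamma1 * P + delta)`. The gain `gamma1` acts per
#' cell; `gamma2..gamma5` act on populations normalized by the
#' characteristic marrow scale of 1e5 cells.
#'
#' @param params a [normal_parameter_set()].
#' @param regulators named numeric vector with components `S`, `P`, `TDm`
#'   (a full state vector with `TDl` is also accepted).
#' @param delta differentiation-therapy strength, >= 0.
#' @return Named vector `p0, p1, q1, eta1, eta2`.
#' @export
evaluate_feedback <- function(params, regulators, delta = 0) {
  stopifnot(all(c("S", "P", "TDm") %in% names(regulators)))
  S <- regulators[["S"]]; P <- regulators[["P"]]; TDm <- regulators[["TDm"]]
  if (any(c(S, P, TDm) < 0)) stop("regulator populations must be non-negative")
  if (delta < 0) stop("delta must be non-negative")
  c(p0   = params[["p0_max"]] / (1 + params[["gamma1"]] * P + delta),
    p1   = params[["p1_max"]] / (1 + params[["gamma3"]] * TDm / N0_CELLS),
    q1   = params[["q1_max"]] / (1 + params[["gamma4"]] * TDm / N0_CELLS),
    eta1 = params[["eta1_max"]] / (1 + params[["gamma2"]] * S / N0_CELLS),
    eta2 = params[["eta2_max"]] / (1 + params[["gamma5"]] * S / N0_CELLS))
}

#' Right-hand side of the normal lineage ODEs
#'
#' dS/dt = (2 p0 - 1) eta1 S; dP/dt = 2 (1 - p0) eta1 S + (2 p1 - 1) eta2 P;
#' dTDl/dt = 2 q1 eta2 P - d_l TDl; dTDm/dt = 2 (1 - p1 - q1) eta2 P - d_m TDm,
#' with the effective rates evaluated at the current state.
#'
#' @param state named numeric vector `S, P, TDl, TDm` (non-negative).
#' @inheritParams evaluate_feedback
#' @return Named derivative vector (cells/day).
#' @export
rhs_normal <- function(state, params, delta = 0) {
  state <- state_vec(state)
  if (any(state < 0)) stop("state must be non-negative")
  d <- cpp_rhs_normal(state, par_vec(params), delta)
  setNames(d, c("S", "P", "TDl", "TDm"))
}

state_vec <- function(state) {
  nm <- c("S", "P", "TDl", "TDm")
  if (!is.null(names(state)) && all(nm %in% names(state)))
    state <- state[nm]
  stopifnot(length(state) == 4)
  as.numeric(state)
}

#' Integrate the normal lineage model
#'
#' Adaptive Dormand-Prince integration (rtol 1e-8, atol 1e-3 cells;
#' populations clipped at zero when within the absolute tolerance).
#'
#' @inheritParams rhs_normal
#' @param state0 initial state (`S, P, TDl, TDm`).
#' @param times strictly increasing output times (days); the first element
#'   is the initial time.
#' @param rtol,atol solver tolerances (atol in cells).
#' @return A data frame with columns `t, S, P, TDl, TDm`.
#' @export
integrate_lineage <- function(params, state0, times, delta = 0,
                              rtol = 1e-8, atol = 1e-3) {
  state0 <- state_vec(state0)
  if (any(state0 < 0)) stop("state0 must be non-negative")
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least two points")
  m <- cpp_integrate_normal(state0, par_vec(params), times, delta, rtol,
                            atol)
  out <- data.frame(t = times, S = m[, 1], P = m[, 2], TDl = m[, 3],
                    TDm = m[, 4])
  out
}

#' Find the steady state of the normal lineage model
#'
#' Integrates until the relative derivative norm
#' `max |dX/dt| / (1 + |X|)` stays below `tol` across a 100-day window,
#' with a hard cap of `tmax` simulated days (40,000 by default: the
#' slowest accepted parameter sets relax on multi-thousand-day
#' timescales).
#'
#' @inheritParams integrate_lineage
#' @param tol steady-state tolerance on the relative derivative norm.
#' @param tmax maximum simulated time (days).
#' @return List with `state` (named), `converged` (logical) and `t`.
#' @export
find_steady_state <- function(params, state0 = c(S = 1e3, P = 0, TDl = 0,
                                                 TDm = 0),
                              tol = 1e-8, tmax = 40000) {
  state0 <- state_vec(state0)
  if (any(state0 < 0)) stop("state0 must be non-negative")
  res <- cpp_steady_normal(state0, par_vec(params), tol, 100, tmax)
  st <- as.numeric(res$state)
  if (isTRUE(res$converged) && all(st > 0))
    st <- polish_steady(params, st)
  list(state = setNames(st, c("S", "P", "TDl", "TDm")),
       converged = isTRUE(res$converged), t = res$t)
}

# Newton refinement of a positive equilibrium to machine precision; falls
# back to the unpolished state if the iteration leaves the positive cone.
polish_steady <- function(params, state, max_iter = 25) {
  y <- state
  for (k in seq_len(max_iter)) {
    f <- cpp_rhs_normal(y, par_vec(params), 0)
    if (max(abs(f) / (1 + abs(y))) < 1e-13) break
    J <- normal_jacobian(params, y)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(state)
    ynew <- y - step
    if (any(ynew <= 0)) return(state)
    if (max(abs(ynew - y) / y) > 0.5) return(state)   # diverging
    y <- ynew
  }
  y
}

#' Closed-form fixed-point identities of the positive equilibrium
#'
#' At a positive equilibrium, dS/dt = 0 with S > 0 forces p0 = 1/2, hence
#' `P = (2 p0_max - 1) / gamma1 - delta-free`; the progenitor balance gives
#' `eta1(S) S = (1 - 2 p1) eta2(S) P`, and the terminal balances give
#' `TDl = 2 q1 eta2 P / d_l` and `TDm = 2 (1 - p1 - q1) eta2 P / d_m`.
#' Returns the maximal relative violation of these four identities at a
#' claimed equilibrium, for verification.
#'
#' @inheritParams rhs_normal
#' @param state claimed positive equilibrium.
#' @return Maximum relative error over the four identities.
#' @export
fixed_point_residual <- function(params, state) {
  state <- state_vec(state)
  S <- state[1]; P <- state[2]; TDl <- state[3]; TDm <- state[4]
  r <- evaluate_feedback(params, c(S = S, P = P, TDm = TDm))
  p_bar <- (2 * params[["p0_max"]] - 1) / params[["gamma1"]]
  errs <- c(
    abs(P - p_bar) / p_bar,
    abs(r[["eta1"]] * S - (1 - 2 * r[["p1"]]) * r[["eta2"]] * P) /
      (r[["eta1"]] * S),
    abs(TDl - 2 * r[["q1"]] * r[["eta2"]] * P / params[["d_l"]]) / TDl,
    abs(TDm - 2 * (1 - r[["p1"]] - r[["q1"]]) * r[["eta2"]] * P /
          params[["d_m"]]) / TDm)
  max(errs)
}

# Numerical Jacobian of the normal RHS (central differences), used for
# node/spiral classification of equilibria.
normal_jacobian <- function(params, state, delta = 0, h_rel = 1e-6) {
  state <- state_vec(state)
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    h <- h_rel * max(abs(state[j]), 1)
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (cpp_rhs_normal(up, par_vec(params), delta) -
               cpp_rhs_normal(dn, par_vec(params), delta)) / (up[j] - dn[j])
  }
  J
}
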