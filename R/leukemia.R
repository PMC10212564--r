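#' Dual normal/leukemic parameter set
#'
#' The leukemic lineage shares the feedback architecture of the normal
#' lineage; by default the only difference is a weaker negative feedback
#' on leukemic stem-cell self-renewal (`gamma1L = gamma1L_ratio * gamma1`,
#' default ratio 0.5), which makes the leukemic clone less responsive to
#' crowding and gives it a competitive advantage. The maximal leukemic
#' self-renewal fraction is constrained to `p0_maxL <= p0_max`.
#'
#' @param normal a [normal_parameter_set()].
#' @param gamma1L_ratio ratio `gamma1L / gamma1`, in (0, 1].
#' @param p0_maxL_ratio ratio `p0_maxL / p0_max`, in (0, 1].
#' @param overrides optional named list overriding individual leukemic
#'   fields (same names as the normal set).
#' @return Object of class `dual_params` with elements `normal` and
#'   `leukemic`.
#' @export
dual_parameter_set <- function(normal, gamma1L_ratio = 0.5,
                               p0_maxL_ratio = 1, overrides = NULL) {
  stopifnot(gamma1L_ratio > 0, p0_maxL_ratio > 0, p0_maxL_ratio <= 1)
  leuk <- unclass(normal)
  leuk[["gamma1"]] <- leuk[["gamma1"]] * gamma1L_ratio
  leuk[["p0_max"]] <- leuk[["p0_max"]] * p0_maxL_ratio
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(leuk))
    if (length(bad)) stop("unknown leukemic fields: ",
                          paste(bad, collapse = ", "))
    leuk[names(overrides)] <- unlist(overrides)
  }
  if (leuk[["p0_max"]] > unclass(normal)[["p0_max"]] + 1e-12)
    stop("p0_maxL must not exceed the normal p0_max")
  if (leuk[["p0_max"]] <= 0.5)
    stop("p0_maxL must exceed 0.5 for a viable leukemic lineage")
  structure(list(normal = normal, leukemic = params_from_vector(leuk)),
            class = "dual_params")
}

#' @export
print.dual_params <- function(x, ...) {
  cat("<dual_params>\n normal:\n")
  print(unclass(x$normal))
  cat(" leukemic:\n")
  print(unclass(x$leukemic))
  invisible(x)
}

dual_state_vec <- function(state) {
  nm <- c("S", "P", "TDl", "TDm", "SL", "PL", "TDlL", "TDmL")
  if (!is.null(names(state)) && all(nm %in% names(state)))
    state <- state[nm]
  stopifnot(length(state) == 8)
  as.numeric(state)
}

therapy_vec <- function(therapy) {
  if (is.null(therapy)) return(c(0, 0, 1, 0))
  c(therapy$tki_death_S, therapy$tki_death_P, therapy$tki_division_factor,
    therapy$delta)
}

#' Right-hand side of the dual normal/leukemic system
#'
#' Both lineages follow the branched lineage equations, with all feedback
#' evaluated on total (normal + leukemic) regulator populations. During
#' TKI therapy the leukemic lineage receives proliferation-dependent kill
#' terms and a reduced maximal stem-cell division rate; the
#' differentiation-therapy strength enters both lineages' p0.
#'
#' @param state named vector `S, P, TDl, TDm, SL, PL, TDlL, TDmL`.
#' @param dual a [dual_parameter_set()].
#' @param therapy optional [therapy_config()]; `NULL` means untreated.
#' @return Named derivative vector (cells/day).
#' @export
rhs_dual <- function(state, dual, therapy = NULL) {
  state <- dual_state_vec(state)
  if (any(state < 0)) stop("state must be non-negative")
  d <- cpp_rhs_dual(state, par_vec(dual$normal), par_vec(dual$leukemic),
                    therapy_vec(therapy))
  setNames(d, c("S", "P", "TDl", "TDm", "SL", "PL", "TDlL", "TDmL"))
}

integrate_dual <- function(state0, dual, times, therapy = NULL,
                           rtol = 1e-8, atol = 1e-3) {
  m <- cpp_integrate_dual(dual_state_vec(state0), par_vec(dual$normal),
                          par_vec(dual$leukemic), times,
                          therapy_vec(therapy), rtol, atol)
  data.frame(t = times, S = m[, 1], P = m[, 2], TDl = m[, 3], TDm = m[, 4],
             SL = m[, 5], PL = m[, 6], TDlL = m[, 7], TDmL = m[, 8])
}

#' Simulate CML development
#'
#' Starts the normal lineage at its untreated steady state, introduces
#' `n_seed_LSC` leukemic stem cells at time 0, and integrates the
#' untreated dual system.
#'
#' @param dual a [dual_parameter_set()].
#' @param n_seed_LSC leukemic stem cells introduced at time 0.
#' @param t_span simulated time (days).
#' @param dt_out output sampling interval (days).
#' @return Dual trajectory data frame with leukemic fractions
#'   (`frac_S, frac_P, frac_TD`) appended.
#' @export
simulate_cml <- function(dual, n_seed_LSC = 1e4, t_span = 3000,
                         dt_out = 5) {
  st <- find_steady_state(dual$normal)
  if (!st$converged) stop("normal lineage did not reach steady state")
  y0 <- c(st$state, SL = n_seed_LSC, PL = 0, TDlL = 0, TDmL = 0)
  times <- unique(c(seq(0, t_span, by = dt_out), t_span))
  tr <- integrate_dual(y0, dual, times)
  add_leukemic_fractions(tr)
}

add_leukemic_fractions <- function(tr) {
  tot <- function(a, b) ifelse(a + b > 0, b / (a + b), 0)
  tr$frac_S <- tot(tr$S, tr$SL)
  tr$frac_P <- tot(tr$P, tr$PL)
  tr$frac_TD <- tot(tr$TDl + tr$TDm, tr$TDlL + tr$TDmL)
  tr
}

#' Leukemic fitness ratio
#'
#' Ratio of characteristic effective self-renewal fractions of leukemic
#' and normal stem cells at a characteristic progenitor level `N_char`:
#' `p0L(N) / p0(N)` with `p0(N) = p0_max / (1 + gamma1 N)`.
#'
#' @param dual a [dual_parameter_set()].
#' @param N_char characteristic MPP population (cells), default 1e5.
#' @return The fitness ratio (dimensionless).
#' @export
fitness <- function(dual, N_char = 1e5) {
  n <- unclass(dual$normal); l <- unclass(dual$leukemic)
  p0L <- l[["p0_max"]] / (1 + l[["gamma1"]] * N_char)
  p0 <- n[["p0_max"]] / (1 + n[["gamma1"]] * N_char)
  unname(p0L / p0)
}

#' Sweep leukemic stem-cell parameters over a cohort
#'
#' For each combination of `p0_maxL / p0_max` and `gamma1L / gamma1`,
#' simulates CML development in every cohort member and records the
#' proportion in which leukemic cells take over the terminal compartment
#' (leukemic fraction of `TDl + TDm` at the evaluation horizon >= 0.5).
#'
#' @param cohort a `cohort` object.
#' @param p0maxL_ratio_grid,gamma1L_ratio_grid ratio grids.
#' @param horizon evaluation horizon (days).
#' @param n_seed_LSC leukemic stem cells introduced at time 0.
#' @return Data frame `p0maxL_ratio, gamma1L_ratio, fraction_takeover,
#'   mean_fitness`.
#' @export
sweep_leukemic_parameters <- function(cohort,
                                      p0maxL_ratio_grid = seq(0.6, 1, 0.1),
                                      gamma1L_ratio_grid = seq(0.1, 0.6, 0.1),
                                      horizon = 3000, n_seed_LSC = 1e4) {
  stopifnot(length(cohort) > 0)
  grid <- expand.grid(p0maxL_ratio = p0maxL_ratio_grid,
                      gamma1L_ratio = gamma1L_ratio_grid)
  grid$fraction_takeover <- NA_real_
  grid$mean_fitness <- NA_real_
  for (g in seq_len(nrow(grid))) {
    take <- logical(length(cohort)); fit <- numeric(length(cohort))
    for (i in seq_along(take)) {
      dual <- dual_parameter_set(cohort_member(cohort, i),
                                 gamma1L_ratio = grid$gamma1L_ratio[g],
                                 p0_maxL_ratio = grid$p0maxL_ratio[g])
      y0 <- c(cohort$steady[i, ], SL = n_seed_LSC, PL = 0, TDlL = 0,
              TDmL = 0)
      tr <- integrate_dual(y0, dual, c(0, horizon))
      end <- tr[nrow(tr), ]
      take[i] <- (end$TDlL + end$TDmL) >=
        0.5 * (end$TDl + end$TDm + end$TDlL + end$TDmL)
      fit[i] <- fitness(dual)
    }
    grid$fraction_takeover[g] <- mean(take)
    grid$mean_fitness[g] <- mean(fit)
  }
  grid
}
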