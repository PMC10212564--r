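#' Acute single-compartment depletion experiment
#'
#' Starts at the untreated steady state, instantaneously removes a
#' fraction of one compartment at t = 0, and follows the free recovery.
#' Transient metrics record the peak relative change of the effective
#' division rates and of the S and P compartments, and whether the
#' system returned to within 1% of the pre-perturbation equilibrium.
#'
#' @param params a [normal_parameter_set()].
#' @param compartment one of `"S", "P", "TDl", "TDm"`.
#' @param fraction depleted fraction in `[0, 1]`.
#' @param t_span follow-up time (days).
#' @param dt_out output interval (days).
#' @return List: `trajectory`, `metrics` (peak relative changes),
#'   `recovered`, `equilibrium`.
#' @export
simulate_depletion <- function(params, compartment = "TDm", fraction,
                               t_span = 300, dt_out = 0.5) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  stopifnot(compartment %in% c("S", "P", "TDl", "TDm"))
  st <- find_steady_state(params)
  if (!st$converged) stop("no steady state for these parameters")
  eq <- st$state
  y0 <- eq
  y0[compartment] <- y0[compartment] * (1 - fraction)
  tr <- integrate_lineage(params, y0, seq(0, t_span, by = dt_out))
  rates <- t(apply(tr[, c("S", "P", "TDl", "TDm")], 1, function(s)
    evaluate_feedback(params, c(S = unname(s[1]), P = unname(s[2]),
                                TDm = unname(s[4])))))
  rates_eq <- evaluate_feedback(params, c(S = eq[["S"]], P = eq[["P"]],
                                          TDm = eq[["TDm"]]))
  peak <- function(x, ref) max(abs(x - ref)) / ref
  metrics <- c(eta1 = peak(rates[, "eta1"], rates_eq[["eta1"]]),
               eta2 = peak(rates[, "eta2"], rates_eq[["eta2"]]),
               S = peak(tr$S, eq[["S"]]), P = peak(tr$P, eq[["P"]]))
  final <- as.numeric(tr[nrow(tr), c("S", "P", "TDl", "TDm")])
  recovered <- max(abs(final - eq) / eq) < 0.01
  list(trajectory = tr, metrics = metrics, recovered = recovered,
       equilibrium = eq)
}

#' Transplant protocol
#'
#' Host depletion fractions mimic sublethal irradiation; the graft is
#' added to the donor stem or progenitor compartment.
#'
#' @param deplete_S,deplete_P host stem / progenitor depletion fractions.
#' @param deplete_TD depletion fraction of both terminal compartments.
#' @param graft `"HSC"` or `"MPP"`.
#' @param graft_size transplanted cells.
#' @param readout_day readout time (days).
#' @return Object of class `transplant_protocol`.
#' @export
transplant_protocol <- function(deplete_S = 0.55, deplete_P = 0.35,
                                deplete_TD = 0.10, graft = "HSC",
                                graft_size = 4000, readout_day = 35) {
  stopifnot(all(c(deplete_S, deplete_P, deplete_TD) >= 0),
            all(c(deplete_S, deplete_P, deplete_TD) <= 1),
            graft %in% c("HSC", "MPP"), graft_size >= 0, readout_day > 0)
  structure(list(deplete_S = deplete_S, deplete_P = deplete_P,
                 deplete_TD = deplete_TD, graft = graft,
                 graft_size = graft_size, readout_day = readout_day),
            class = "transplant_protocol")
}

#' Simulate a stem- or progenitor-graft transplant
#'
#' Host and donor lineages carry identical parameters (two labeled copies
#' of the same leukemic lineage). The host starts at the single-lineage
#' steady state, is depleted per protocol, the graft is added to the
#' donor compartment, and the labeled dual system is integrated to the
#' readout time.
#'
#' @param params a [normal_parameter_set()] shared by host and donor.
#' @param protocol a [transplant_protocol()].
#' @return List: `donor` (donor-derived compartment counts at readout),
#'   `donor_myeloid_frac`, `donor_lymphoid_frac` (fractions among
#'   donor-derived terminal cells), `trajectory`.
#' @export
simulate_transplant <- function(params, protocol) {
  stopifnot(inherits(protocol, "transplant_protocol"))
  st <- find_steady_state(params)
  if (!st$converged) stop("no steady state for these parameters")
  host <- st$state
  host["S"] <- host["S"] * (1 - protocol$deplete_S)
  host["P"] <- host["P"] * (1 - protocol$deplete_P)
  host["TDl"] <- host["TDl"] * (1 - protocol$deplete_TD)
  host["TDm"] <- host["TDm"] * (1 - protocol$deplete_TD)
  donor <- c(SL = 0, PL = 0, TDlL = 0, TDmL = 0)
  donor[if (protocol$graft == "HSC") "SL" else "PL"] <- protocol$graft_size
  dual <- dual_parameter_set(params, gamma1L_ratio = 1, p0_maxL_ratio = 1)
  times <- seq(0, protocol$readout_day, by = 0.5)
  tr <- integrate_dual(c(host, donor), dual, times)
  end <- tr[nrow(tr), ]
  dterm <- end$TDlL + end$TDmL
  list(donor = c(S = end$SL, P = end$PL, TDl = end$TDlL, TDm = end$TDmL),
       donor_myeloid_frac = if (dterm > 0) end$TDmL / dterm else NA_real_,
       donor_lymphoid_frac = if (dterm > 0) end$TDlL / dterm else NA_real_,
       trajectory = tr)
}

#' Transplant-consistency cohort filter
#'
#' Keeps members for which a stem-cell graft yields a donor-derived
#' myeloid majority and a progenitor graft yields a donor-derived
#' lymphoid majority at the readout time.
#'
#' @param cohort a `cohort` object.
#' @param protocol base [transplant_protocol()]; the graft type is set
#'   internally for the two arms.
#' @return Filtered `cohort`.
#' @export
transplant_filter <- function(cohort, protocol = transplant_protocol()) {
  keep <- vapply(seq_len(length(cohort)), function(i) {
    ps <- cohort_member(cohort, i)
    ph <- protocol; ph$graft <- "HSC"
    pm <- protocol; pm$graft <- "MPP"
    h <- simulate_transplant(ps, ph)
    m <- simulate_transplant(ps, pm)
    isTRUE(h$donor_myeloid_frac > 0.5) &&
      isTRUE(m$donor_lymphoid_frac > 0.5)
  }, logical(1))
  subset_cohort(cohort, keep, "transplant")
}

#' Early myeloid-versus-lymphoid fate bias
#'
#' From a progenitor pool with empty terminal compartments, the early
#' fluxes into the myeloid and lymphoid branches are proportional to
#' `1 - p1 - q1` and `q1`; output is myeloid-biased when
#' `1 - p1 > 2 q1`.
#'
#' @param rates effective rates from [evaluate_feedback()].
#' @return `"myeloid"`, `"lymphoid"`, or `"balanced"`.
#' @export
early_fate_predictor <- function(rates) {
  lhs <- 1 - rates[["p1"]]
  rhs <- 2 * rates[["q1"]]
  if (isTRUE(all.equal(lhs, rhs))) return("balanced")
  if (lhs > rhs) "myeloid" else "lymphoid"
}
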