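#' TKI / combination therapy configuration
#'
#' TKI action is modeled as proliferation-dependent death of leukemic
#' stem and progenitor cells (kill fluxes `tki_death_S * eta1L * SL` and
#' `tki_death_P * eta2L * PL`) plus a reduction of the maximal leukemic
#' stem-cell division rate (quiescence induction). Differentiation
#' therapy adds the constant `delta` to the self-renewal denominators of
#' both lineages. The default kill multipliers were frozen after
#' calibrating on the reference patient so that an early (6-month)
#' therapy start yields a biphasic decline reaching MR3, an intermediate
#' (18-month) start plateaus above the MR3 level, and a late (36-month)
#' start leaves transcripts essentially unchanged (see
#' [calibrate_tki()]).
#'
#' @param start_month therapy start, months after CML initiation.
#' @param tki_death_S kill multiplier on the leukemic stem-cell division
#'   rate.
#' @param tki_death_P kill multiplier on the leukemic progenitor division
#'   rate.
#' @param tki_division_factor factor in (0, 1] applied to the maximal
#'   leukemic stem-cell division rate during therapy.
#' @param delta differentiation-therapy strength (dimensionless, >= 0).
#' @param duration_months treated duration (months).
#' @return Object of class `therapy_config`.
#' @export
therapy_config <- function(start_month = 6, tki_death_S = 0.4,
                           tki_death_P = 1, tki_division_factor = 0.5,
                           delta = 0, duration_months = 50) {
  stopifnot(start_month >= 0, tki_death_S >= 0, tki_death_P >= 0,
            tki_division_factor > 0, tki_division_factor <= 1,
            delta >= 0, duration_months > 0)
  structure(list(start_month = start_month, tki_death_S = tki_death_S,
                 tki_death_P = tki_death_P,
                 tki_division_factor = tki_division_factor, delta = delta,
                 duration_months = duration_months),
            class = "therapy_config")
}

#' BCR-ABL1 transcript ratio
#'
#' `(TDlL + TDmL) / (TDlL + TDmL + 2 (TDl + TDm))`: the leukemic share of
#' terminal cells with the normal contribution doubled, mimicking the
#' control-gene normalization of the clinical assay. Multiply by 100 for
#' the percent (International Scale-like) value.
#'
#' @param state named state (or one trajectory row) containing
#'   `TDl, TDm, TDlL, TDmL`.
#' @return Ratio in `[0, 1]`.
#' @export
transcript_ratio <- function(state) {
  l <- as.numeric(state[["TDlL"]]) + as.numeric(state[["TDmL"]])
  n <- as.numeric(state[["TDl"]]) + as.numeric(state[["TDm"]])
  if (l + n <= 0) stop("transcript ratio undefined: no terminal cells")
  l / (l + 2 * n)
}

# NA instead of an error when every terminal compartment is empty
# (used inside cohort sweeps, where an extinguished marrow must not
# abort the run; NA months never count as MR3).
transcript_ratio_safe <- function(state) {
  l <- as.numeric(state[["TDlL"]]) + as.numeric(state[["TDmL"]])
  n <- as.numeric(state[["TDl"]]) + as.numeric(state[["TDm"]])
  if (l + n <= 0) return(NA_real_)
  l / (l + 2 * n)
}

#' Simulate TKI (or combination) therapy for one virtual patient
#'
#' CML development is simulated from the normal steady state up to the
#' therapy start; therapy terms are then switched on and the treated
#' dual system integrated for the configured duration. The transcript
#' percentage is recorded monthly (month 0 = therapy start).
#'
#' @param dual a [dual_parameter_set()].
#' @param cfg a [therapy_config()].
#' @param n_seed_LSC leukemic stem cells seeding CML at time 0.
#' @return List: `series` (monthly `transcript_series`), `trajectory`
#'   (treated dual trajectory, `t` in days since therapy start),
#'   `hscl_fraction_at_start`, `state_at_start`.
#' @export
simulate_therapy <- function(dual, cfg, n_seed_LSC = 1e4) {
  stopifnot(inherits(cfg, "therapy_config"))
  start_day <- cfg$start_month * DAYS_PER_MONTH
  if (start_day > 0) {
    dev <- simulate_cml(dual, n_seed_LSC = n_seed_LSC, t_span = start_day,
                        dt_out = max(start_day / 200, 1))
    y0 <- as.numeric(dev[nrow(dev), c("S", "P", "TDl", "TDm", "SL", "PL",
                                      "TDlL", "TDmL")])
  } else {
    st <- find_steady_state(dual$normal)
    y0 <- c(st$state, n_seed_LSC, 0, 0, 0)
  }
  names(y0) <- c("S", "P", "TDl", "TDm", "SL", "PL", "TDlL", "TDmL")
  hscl <- unname(y0["SL"] / (y0["S"] + y0["SL"]))
  times <- seq(0, cfg$duration_months * DAYS_PER_MONTH,
               by = DAYS_PER_MONTH / 2)
  tr <- integrate_dual(y0, dual, times, therapy = cfg)
  series <- make_transcript_series(tr, schedule = 0:cfg$duration_months)
  list(series = series, trajectory = add_leukemic_fractions(tr),
       hscl_fraction_at_start = hscl, state_at_start = y0)
}

#' Time to major molecular response (MR3)
#'
#' First scheduled month at which the transcript percentage falls
#' strictly below `threshold_pct` (default 0.1%, the MR3 level).
#'
#' @param series a `transcript_series` data frame.
#' @param threshold_pct percent threshold.
#' @return The month, or `NA` when the threshold is never reached.
#' @export
time_to_mr3 <- function(series, threshold_pct = 0.1) {
  stopifnot(nrow(series) > 0)
  hit <- which(!is.na(series$bcr_abl_pct) &
                 series$bcr_abl_pct < threshold_pct)
  if (length(hit) == 0) NA_real_ else series$month[hit[1]]
}

#' Differentiation-therapy strength sweep over a cohort
#'
#' For each strength `delta`, runs combination therapy on every cohort
#' member and records the proportion achieving MR3 within the horizon.
#' The `delta = 0` column is TKI monotherapy.
#'
#' By default a member only counts as a responder if its normal
#' hematopoiesis remains viable at the horizon (normal stem pool at
#' least one cell): excessive suppression of self-renewal
#' (`delta > 2 p0_max - 1`) extinguishes the normal stem compartment,
#' and a transcript dip achieved by wiping out both stem pools is not a
#' therapeutic success. This produces the non-monotone efficacy profile:
#' rising MR3 proportions at moderate `delta`, then decline as more
#' members lose normal hematopoiesis.
#'
#' @param cohort a `cohort` object.
#' @param delta_grid differentiation strengths to sweep.
#' @param cfg base [therapy_config()] (its `delta` is overridden).
#' @param gamma1L_ratio,p0_maxL_ratio leukemic overrides applied to every
#'   member.
#' @param mr3_horizon months within which MR3 must be reached.
#' @param require_viable_hematopoiesis require the normal stem pool to
#'   survive to the horizon for a member to count as a responder.
#' @return Data frame `delta, proportion_mr3`, with attributes
#'   `peak_delta` and `peak_proportion`.
#' @export
sweep_delta <- function(cohort, delta_grid = seq(0, 0.6, 0.04),
                        cfg = therapy_config(),
                        gamma1L_ratio = 0.5, p0_maxL_ratio = 1,
                        mr3_horizon = 50,
                        require_viable_hematopoiesis = TRUE) {
  stopifnot(length(cohort) > 0, mr3_horizon <= cfg$duration_months)
  n <- length(cohort)
  hit <- matrix(FALSE, n, length(delta_grid))
  for (i in seq_len(n)) {
    dual <- dual_parameter_set(cohort_member(cohort, i),
                               gamma1L_ratio = gamma1L_ratio,
                               p0_maxL_ratio = p0_maxL_ratio)
    # CML development is delta-independent: compute the start state once
    start_day <- cfg$start_month * DAYS_PER_MONTH
    y0 <- c(cohort$steady[i, ], SL = 1e4, PL = 0, TDlL = 0, TDmL = 0)
    if (start_day > 0) {
      dev <- integrate_dual(y0, dual, c(0, start_day))
      y0 <- as.numeric(dev[2, -1])
    }
    times <- seq(0, mr3_horizon * DAYS_PER_MONTH, by = DAYS_PER_MONTH)
    for (k in seq_along(delta_grid)) {
      ck <- cfg; ck$delta <- delta_grid[k]
      tr <- integrate_dual(y0, dual, times, therapy = ck)
      pct <- 100 * vapply(seq_len(nrow(tr)), function(r)
        transcript_ratio_safe(tr[r, ]), numeric(1))
      hit[i, k] <- any(pct < 0.1, na.rm = TRUE)
      if (require_viable_hematopoiesis && tr$S[nrow(tr)] < 1)
        hit[i, k] <- FALSE
    }
  }
  out <- data.frame(delta = delta_grid, proportion_mr3 = colMeans(hit))
  pk <- which.max(out$proportion_mr3)
  attr(out, "peak_delta") <- out$delta[pk]
  attr(out, "peak_proportion") <- out$proportion_mr3[pk]
  out
}

#' Calibrate TKI kill multipliers on a reference patient
#'
#' Searches a small grid of kill multipliers and returns the first
#' configuration producing a biphasic transcript decline that reaches MR3
#' within the target window under an early therapy start. Used once to
#' freeze the package defaults; not run per cohort.
#'
#' @param dual reference patient's [dual_parameter_set()].
#' @param kill_S_grid,kill_P_grid candidate multipliers.
#' @param target_window acceptable months-to-MR3 range.
#' @param start_month therapy start used for calibration.
#' @return A [therapy_config()], or `NULL` if no grid point qualifies.
#' @export
calibrate_tki <- function(dual, kill_S_grid = c(0.2, 0.5, 1),
                          kill_P_grid = c(2, 5, 10),
                          target_window = c(12, 18), start_month = 6) {
  for (kP in kill_P_grid) for (kS in kill_S_grid) {
    cfg <- therapy_config(start_month = start_month, tki_death_S = kS,
                          tki_death_P = kP)
    res <- simulate_therapy(dual, cfg)
    tm <- time_to_mr3(res$series)
    if (!is.na(tm) && tm >= target_window[1] && tm <= target_window[2] &&
        is_biphasic(res$series))
      return(cfg)
  }
  NULL
}

# Biphasic decline heuristic: both early and late segments decline on the
# log scale, with the early log-slope at least twice the late log-slope.
is_biphasic <- function(series, split_month = 6) {
  v <- pmax(series$bcr_abl_pct, 1e-8)
  early <- series$month <= split_month
  if (sum(early) < 2 || sum(!early) < 2) return(FALSE)
  s1 <- stats::coef(stats::lm(log(v[early]) ~ series$month[early]))[2]
  s2 <- stats::coef(stats::lm(log(v[!early]) ~ series$month[!early]))[2]
  s1 < 0 && s2 < 0 && s1 < 2 * s2
}
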