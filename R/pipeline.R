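#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end pipeline; a stored configuration
#' plus its seed regenerates all artifacts exactly. Serialized as JSON.
#'
#' @param n_iter grid-search iterations.
#' @param seed master seed; stage seeds are derived from it.
#' @param ranges sampling ranges.
#' @param gamma5_min feedforward filter threshold.
#' @param protocol a [transplant_protocol()].
#' @param therapy a [therapy_config()].
#' @param gamma1L_ratio,p0_maxL_ratio leukemic overrides for therapy runs.
#' @param delta_grid differentiation-strength grid.
#' @param responder_horizon months-to-MR3 horizon defining a responder
#'   for prognostics.
#' @param mr3_horizon months-to-MR3 horizon for the delta sweep.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_iter = 2e4, seed = 1,
                            ranges = default_sampling_ranges(),
                            gamma5_min = 0.01,
                            protocol = transplant_protocol(),
                            therapy = therapy_config(),
                            gamma1L_ratio = 0.5, p0_maxL_ratio = 1,
                            delta_grid = seq(0, 0.6, 0.04),
                            responder_horizon = 18, mr3_horizon = 50) {
  structure(list(n_iter = n_iter, seed = seed, ranges = ranges,
                 gamma5_min = gamma5_min, protocol = protocol,
                 therapy = therapy, gamma1L_ratio = gamma1L_ratio,
                 p0_maxL_ratio = p0_maxL_ratio, delta_grid = delta_grid,
                 responder_horizon = responder_horizon,
                 mr3_horizon = mr3_horizon),
            class = "pipeline_config")
}

#' Run TKI therapy on every cohort member
#'
#' CML is developed from each member's stored steady state to the therapy
#' start, then the treated system is simulated; monthly transcript series
#' and times to MR3 are collected.
#'
#' @param cohort a `cohort` object (with steady states).
#' @param cfg a [therapy_config()].
#' @param gamma1L_ratio,p0_maxL_ratio leukemic overrides.
#' @param n_seed_LSC leukemic stem cells seeding CML.
#' @return List: `series` (list of `transcript_series`), `mr3_month`,
#'   `hscl_fraction_at_start`.
#' @export
run_cohort_therapy <- function(cohort, cfg = therapy_config(),
                               gamma1L_ratio = 0.5, p0_maxL_ratio = 1,
                               n_seed_LSC = 1e4) {
  n <- length(cohort)
  series <- vector("list", n)
  mr3 <- numeric(n); hscl <- numeric(n)
  start_day <- cfg$start_month * DAYS_PER_MONTH
  for (i in seq_len(n)) {
    dual <- dual_parameter_set(cohort_member(cohort, i),
                               gamma1L_ratio = gamma1L_ratio,
                               p0_maxL_ratio = p0_maxL_ratio)
    y0 <- c(cohort$steady[i, ], SL = n_seed_LSC, PL = 0, TDlL = 0,
            TDmL = 0)
    if (start_day > 0) {
      dev <- integrate_dual(y0, dual, c(0, start_day))
      y0 <- setNames(as.numeric(dev[2, -1])[1:8], names(y0))
    }
    hscl[i] <- y0[["SL"]] / (y0[["S"]] + y0[["SL"]])
    times <- seq(0, cfg$duration_months * DAYS_PER_MONTH,
                 by = DAYS_PER_MONTH)
    tr <- integrate_dual(y0, dual, times, therapy = cfg)
    series[[i]] <- make_transcript_series(tr,
                                          schedule = 0:cfg$duration_months,
                                          patient_id = cohort$id[i])
    mr3[i] <- time_to_mr3(series[[i]])
  }
  list(series = series, mr3_month = mr3, hscl_fraction_at_start = hscl)
}

write_stage_csv <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", provenance), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stage_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Run the end-to-end pipeline
#'
#' Chains cohort construction, the feedforward and transplant filters,
#' cohort-wide TKI therapy, prognostic ROC evaluation, and the
#' differentiation-strength sweep, writing each stage's output under
#' `outdir` with provenance headers.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @param verbose print stage progress to stderr.
#' @return Invisible list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile(),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (verbose) message(sprintf(...))
  prov <- sprintf("seed=%d n_iter=%d", config$seed, config$n_iter)
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  note("stage 1/5: grid search (%d iterations)", config$n_iter)
  cohort <- run_grid_search(config$n_iter, seed = config$seed,
                            ranges = config$ranges)
  write_cohort(cohort, file.path(outdir, "cohort_accepted.csv"))

  note("stage 2/5: feedforward filter (%d members in)", length(cohort))
  ff <- filter_feedforward(cohort, config$gamma5_min)
  write_cohort(ff, file.path(outdir, "cohort_feedforward.csv"))

  note("stage 3/5: transplant filter (%d members in)", length(ff))
  tp <- transplant_filter(ff, config$protocol)
  write_cohort(tp, file.path(outdir, "cohort_transplant.csv"))
  if (length(tp) == 0) stop("pipeline: no members survived the filters")

  note("stage 4/5: TKI therapy on %d members", length(tp))
  th <- run_cohort_therapy(tp, config$therapy,
                           gamma1L_ratio = config$gamma1L_ratio,
                           p0_maxL_ratio = config$p0_maxL_ratio)
  outcomes <- data.frame(id = tp$id,
                         hscl_fraction = th$hscl_fraction_at_start,
                         mr3_month = th$mr3_month)
  write_stage_csv(outcomes, file.path(outdir, "therapy_outcomes.csv"), prov)

  note("stage 5/5: prognostics and delta sweep")
  labels <- !is.na(th$mr3_month) & th$mr3_month <= config$responder_horizon
  prog <- NULL
  if (length(unique(labels)) == 2) {
    prog <- compare_windows(th$series, labels)
    write_stage_csv(prog, file.path(outdir, "prognostics.csv"), prov)
  }
  sweep <- sweep_delta(tp, delta_grid = config$delta_grid,
                       cfg = config$therapy,
                       gamma1L_ratio = config$gamma1L_ratio,
                       p0_maxL_ratio = config$p0_maxL_ratio,
                       mr3_horizon = config$mr3_horizon)
  write_stage_csv(sweep, file.path(outdir, "delta_sweep.csv"), prov)

  invisible(list(cohort = cohort, feedforward = ff, transplant = tp,
                 therapy = th, prognostics = prog, delta_sweep = sweep,
                 outdir = outdir))
}
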