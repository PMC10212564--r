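#' Draw virtual-patient parameter sets
#'
#' Each field is drawn independently and uniformly on its range, with
#' three exceptions documented in [default_sampling_ranges()]: `q1_max`
#' is drawn on `[0, 1 - p1_max]`, `gamma1` is drawn so the progenitor
#' equilibrium `(2 p0_max - 1) / gamma1` falls in the stated MPP band,
#' and `gamma2..gamma5` are drawn log-uniformly. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param n number of parameter sets to draw.
#' @param ranges sampling ranges, see [default_sampling_ranges()].
#' @return Numeric matrix `n x 12` with parameter columns.
#' @export
sample_parameters <- function(n = 1, ranges = default_sampling_ranges()) {
  for (r in ranges)
    if (length(r) != 2 || any(r < 0) || r[1] > r[2])
      stop("invalid sampling range")
  u <- function(nm) runif(n, ranges[[nm]][1], ranges[[nm]][2])
  lu <- function(nm) {
    lo <- max(ranges[[nm]][1], 1e-300)
    exp(runif(n, log(lo), log(ranges[[nm]][2])))
  }
  p0 <- u("p0_max")
  p1 <- u("p1_max")
  q1 <- runif(n, ranges[["q1_max"]][1], ranges[["q1_max"]][2]) * (1 - p1)
  band <- ranges[["gamma1"]]    # target MPP band, cells
  g1 <- runif(n, (2 * p0 - 1) / band[2], (2 * p0 - 1) / band[1])
  m <- cbind(p0_max = p0, p1_max = p1, q1_max = q1,
             eta1_max = u("eta1_max"), eta2_max = u("eta2_max"),
             d_l = u("d_l"), d_m = u("d_m"), gamma1 = g1,
             gamma2 = lu("gamma2"), gamma3 = lu("gamma3"),
             gamma4 = lu("gamma4"), gamma5 = lu("gamma5"))
  m
}

# Population-ordering acceptance test at the steady state reached from a
# small HSC seed: 1e4 < S < P, P in the MPP band, P < TDl < TDm.
ordering_ok <- function(st, band = c(0.5e5, 2e5)) {
  S <- st[1]; P <- st[2]; TDl <- st[3]; TDm <- st[4]
  S > 1e4 && S < P && P > band[1] && P < band[2] && P < TDl && TDl < TDm
}

#' Steady-state acceptance test for one parameter set
#'
#' Integrates from a small HSC seed population to steady state and checks
#' the population-ordering constraints: `1e4 < S < P`, `P` within the MPP
#' band around `1e5` cells, and `P < TDl < TDm`.
#'
#' @param ps a [normal_parameter_set()].
#' @param state0 seed state; default 1e3 HSC and nothing else.
#' @param band MPP acceptance band (cells).
#' @return List with `accepted`, `steady_state`, `converged`.
#' @export
accept_parameter_set <- function(ps, state0 = c(S = 1e3, P = 0, TDl = 0,
                                                TDm = 0),
                                 band = c(0.5e5, 2e5)) {
  st <- find_steady_state(ps, state0)
  ok <- st$converged && ordering_ok(st$state, band)
  list(accepted = ok, steady_state = st$state, converged = st$converged)
}

#' Grid-search construction of a virtual-patient cohort
#'
#' Draws `n_iter` uniform parameter sets and keeps those whose untreated
#' steady state satisfies the population-ordering constraints. The stored
#' provenance (seed, ranges, iteration count) regenerates the cohort
#' exactly.
#'
#' @param n_iter number of sampling iterations.
#' @param seed RNG seed.
#' @param ranges sampling ranges.
#' @return A `cohort` object: accepted parameter sets with ids, their
#'   steady states, and provenance.
#' @export
run_grid_search <- function(n_iter, seed = 1,
                            ranges = default_sampling_ranges()) {
  stopifnot(n_iter >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (n_iter == 0) {
    params <- matrix(numeric(0), 0, 12)
    steady <- matrix(numeric(0), 0, 4)
  } else {
    draws <- sample_parameters(n_iter, ranges)
    res <- cpp_steady_batch(draws, c(1e3, 0, 0, 0), 1e-8, 100, 40000)
    band <- ranges[["gamma1"]]
    keep <- res[, 5] == 1 &
      apply(res[, 1:4, drop = FALSE], 1, ordering_ok, band = band)
    params <- draws[keep, , drop = FALSE]
    steady <- res[keep, 1:4, drop = FALSE]
    for (i in seq_len(nrow(steady)))
      steady[i, ] <- polish_steady(params_from_vector(params[i, ]),
                                   steady[i, ])
  }
  colnames(steady) <- c("S", "P", "TDl", "TDm")
  structure(list(
    params = params, steady = steady,
    id = seq_len(nrow(params)),
    provenance = list(seed = seed, n_iter = n_iter, ranges = ranges,
                      filters = character(0),
                      acceptance_fraction = nrow(params) / max(n_iter, 1))),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d members (from %d iterations, seed %s)\n",
              nrow(x$params), x$provenance$n_iter,
              format(x$provenance$seed)))
  if (length(x$provenance$filters))
    cat(" filters:", paste(x$provenance$filters, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.cohort <- function(x) nrow(x$params)

#' Extract one cohort member as a parameter set
#' @param cohort a `cohort` object.
#' @param i member index.
#' @return A [normal_parameter_set()].
#' @export
cohort_member <- function(cohort, i) {
  params_from_vector(cohort$params[i, ])
}

subset_cohort <- function(cohort, keep, filter_name) {
  cohort$params <- cohort$params[keep, , drop = FALSE]
  cohort$steady <- cohort$steady[keep, , drop = FALSE]
  cohort$id <- cohort$id[keep]
  cohort$provenance$filters <- c(cohort$provenance$filters, filter_name)
  cohort
}

#' Feedforward-gain cohort filter
#'
#' Keeps members whose feedforward gain on the MPP division rate exceeds
#' `gamma5_min`.
#'
#' @param cohort a `cohort` object.
#' @param gamma5_min threshold (per cell); default 0.01.
#' @return Filtered `cohort`.
#' @export
filter_feedforward <- function(cohort, gamma5_min = 0.01) {
  keep <- cohort$params[, "gamma5"] > gamma5_min
  subset_cohort(cohort, keep,
                sprintf("feedforward(gamma5>%g)", gamma5_min))
}

#' Clinic-style transcript series from a dual-lineage trajectory
#'
#' Samples the BCR-ABL1 transcript ratio at scheduled months (percent
#' scale) with optional multiplicative lognormal noise of the given
#' coefficient of variation; values are clipped to `[0, 100]`.
#'
#' @param trajectory dual trajectory data frame (from [simulate_cml()] or
#'   [simulate_therapy()]), with time column `t` in days.
#' @param schedule measurement months.
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   0 disables noise. Uses the current RNG state.
#' @param patient_id identifier carried in the result.
#' @return A `transcript_series` data frame: `patient_id, month,
#'   bcr_abl_pct`.
#' @export
make_transcript_series <- function(trajectory, schedule = 0:12,
                                   noise_cv = 0, patient_id = 1L) {
  stopifnot(noise_cv >= 0)
  tdays <- schedule * DAYS_PER_MONTH
  if (min(tdays) < min(trajectory$t) - 1e-9 ||
      max(tdays) > max(trajectory$t) + 1e-9)
    stop("schedule outside trajectory time span")
  idx <- vapply(tdays, function(d) which.min(abs(trajectory$t - d)),
                integer(1))
  if (max(abs(trajectory$t[idx] - tdays)) > 0.5)
    stop("trajectory does not cover the schedule densely enough")
  pct <- 100 * vapply(idx, function(i)
    transcript_ratio_safe(trajectory[i, ]), numeric(1))
  if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    pct <- pct * exp(stats::rnorm(length(pct), -sdl^2 / 2, sdl))
  }
  structure(data.frame(patient_id = patient_id, month = schedule,
                       bcr_abl_pct = pmin(pmax(pct, 0), 100)),
            class = c("transcript_series", "data.frame"))
}

#' Write / read a cohort as CSV with a JSON provenance sidecar
#'
#' @param cohort a `cohort` object.
#' @param path CSV path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(id = cohort$id, cohort$params, cohort$steady,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(cohort$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
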