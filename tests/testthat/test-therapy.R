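test_that("therapy with zero kill and zero delta is exactly the untreated
           system", {
  dual <- reference_dual()
  y <- c(S = 1e4, P = 8e4, TDl = 2e5, TDm = 3e5,
         SL = 5e3, PL = 4e4, TDlL = 1e5, TDmL = 2e5)
  off <- therapy_config(tki_death_S = 0, tki_death_P = 0,
                        tki_division_factor = 1, delta = 0)
  expect_identical(rhs_dual(y, dual, off), rhs_dual(y, dual, NULL))
})

test_that("transcript ratio limits, scale invariance and errors", {
  st <- c(TDl = 2e5, TDm = 3e5, TDlL = 0, TDmL = 0)
  expect_equal(transcript_ratio(st), 0)
  st2 <- c(TDl = 0, TDm = 0, TDlL = 1e5, TDmL = 1e5)
  expect_equal(transcript_ratio(st2), 1)
  st3 <- c(TDl = 3e5, TDm = 1e5, TDlL = 2e5, TDmL = 2e5)
  expect_equal(transcript_ratio(st3), 1 / 3)
  expect_equal(transcript_ratio(as.list(st3 * 17)), 1 / 3)
  expect_error(transcript_ratio(c(TDl = 0, TDm = 0, TDlL = 0, TDmL = 0)),
               "undefined")
})

test_that("time_to_mr3 detection and threshold monotonicity", {
  s <- fixture_series(c(50, 20, 5, 1, 0.3, 0.09, 0.02))
  expect_equal(time_to_mr3(s), 5)
  expect_true(is.na(time_to_mr3(fixture_series(rep(50, 6)))))
  expect_equal(time_to_mr3(fixture_series(c(10, 0.05, 0.2)),
                           threshold_pct = 0.1), 1)
  set.seed(31)
  for (i in 1:20) {
    vals <- 100 * exp(-cumsum(runif(24, 0, 0.6)))
    s <- fixture_series(vals)
    t1 <- time_to_mr3(s, 0.05); t2 <- time_to_mr3(s, 0.5)
    if (!is.na(t1) && !is.na(t2)) expect_gte(t1, t2)
  }
})

test_that("therapy-timing regimes on the reference patient", {
  dual <- reference_dual(gamma1L_ratio = 0.5)
  runs <- lapply(c(6, 18, 36), function(sm)
    simulate_therapy(dual, therapy_config(start_month = sm)))
  hscl <- vapply(runs, `[[`, numeric(1), "hscl_fraction_at_start")
  expect_true(all(diff(hscl) > 0))       # leukemic load grows with delay
  # early start: biphasic decline reaching MR3
  s6 <- runs[[1]]$series
  expect_false(is.na(time_to_mr3(s6)))
  expect_true(hemopoiesis:::is_biphasic(s6))
  # intermediate start: plateau above MR3, touching the 1-9% band
  s18 <- runs[[2]]$series
  late <- s18$bcr_abl_pct[s18$month >= 24]
  expect_true(is.na(time_to_mr3(s18)))
  expect_true(all(late > 0.1))
  expect_true(any(s18$bcr_abl_pct >= 1 & s18$bcr_abl_pct <= 9))
  # late start: essentially no transcript change
  s36 <- runs[[3]]$series
  expect_true(is.na(time_to_mr3(s36)))
  expect_lt(max(s36$bcr_abl_pct) / min(s36$bcr_abl_pct), 10)
  # final level increases with leukemic stem load at start
  finals <- vapply(runs, function(r) r$series$bcr_abl_pct[51], numeric(1))
  expect_true(all(diff(finals) > 0))
})

test_that("delta = 0 sweep column equals monotherapy outcomes", {
  co <- fixture_cohort()
  expect_gte(length(co), 2)
  cfg <- therapy_config(duration_months = 30)
  sw <- sweep_delta(co, delta_grid = c(0, 0.2), cfg = cfg,
                    gamma1L_ratio = 0.15, mr3_horizon = 30,
                    require_viable_hematopoiesis = FALSE)
  th <- run_cohort_therapy(co, cfg, gamma1L_ratio = 0.15)
  mono <- mean(!is.na(th$mr3_month) & th$mr3_month <= 30)
  expect_equal(sw$proportion_mr3[1], mono)
})

test_that("calibration helper returns a configuration meeting its
           window, or NULL", {
  dual <- reference_dual()
  cfg <- calibrate_tki(dual, kill_S_grid = 0.4, kill_P_grid = 1,
                       target_window = c(20, 40))
  expect_s3_class(cfg, "therapy_config")
  tm <- time_to_mr3(simulate_therapy(dual, cfg)$series)
  expect_true(tm >= 20 && tm <= 40)
  expect_null(calibrate_tki(dual, kill_S_grid = 1e-6,
                            kill_P_grid = 1e-6,
                            target_window = c(1, 2)))
})
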