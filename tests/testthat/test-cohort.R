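test_that("sample_parameters respects ranges and determinism", {
  r <- default_sampling_ranges()
  r$eta1_max <- c(0.05, 0.05)                 # degenerate range
  set.seed(1); a <- sample_parameters(5, r)
  set.seed(1); b <- sample_parameters(5, r)
  expect_identical(a, b)
  expect_true(all(a[, "eta1_max"] == 0.05))
  expect_true(all(a[, "q1_max"] <= (1 - a[, "p1_max"]) * r$q1_max[2]))
  # gamma1 is co-designed with the MPP band
  P_eq <- (2 * a[, "p0_max"] - 1) / a[, "gamma1"]
  expect_true(all(P_eq >= 0.5e5 & P_eq <= 2e5))
  r$d_l <- c(2, 1)
  expect_error(sample_parameters(2, r), "range")
})

test_that("uniform sampling has the right mean", {
  set.seed(2)
  x <- sample_parameters(1e4)[, "p0_max"]
  se <- (0.5 / sqrt(12)) / sqrt(1e4)
  expect_lt(abs(mean(x) - 0.75), 3 * se)
})

test_that("acceptance applies the population-ordering constraints", {
  ps <- fixture_params()   # built with P = 1e5 by construction
  acc <- accept_parameter_set(ps)
  expect_true(acc$accepted)
  expect_equal(acc$steady_state[["P"]], 1e5, tolerance = 1e-4)
  # reversing the death rates reverses the TDl/TDm ordering
  bad <- unclass(ps)
  bad[["d_l"]] <- 0.4; bad[["d_m"]] <- 0.003
  bad <- hemopoiesis:::params_from_vector(bad)
  expect_false(accept_parameter_set(bad)$accepted)
  # verdict does not depend on the seed population size
  acc2 <- accept_parameter_set(ps, state0 = c(S = 1e2, P = 0, TDl = 0,
                                              TDm = 0))
  expect_identical(acc$accepted, acc2$accepted)
  expect_lt(max(abs(acc$steady_state - acc2$steady_state) /
                  acc$steady_state), 1e-5)
})

test_that("grid search is reproducible and filters behave", {
  co1 <- fixture_cohort()
  co2 <- run_grid_search(2500, seed = 7, ranges = enriched_sampling_ranges())
  expect_identical(co1$params, co2$params)
  expect_identical(co1$steady, co2$steady)
  expect_identical(length(run_grid_search(0, seed = 1)), 0L)
  # members reproduce their stored steady states on re-integration
  if (length(co1) > 0) {
    ps <- cohort_member(co1, 1)
    st <- find_steady_state(ps)
    expect_lt(max(abs(st$state - co1$steady[1, ]) /
                    pmax(co1$steady[1, ], 1)), 1e-6)
  }
  expect_identical(length(filter_feedforward(co1, 0)), length(co1))
  expect_identical(length(filter_feedforward(co1, Inf)), 0L)
  ff <- filter_feedforward(co1, 0.01)
  expect_true(all(ff$params[, "gamma5"] > 0.01))
})

test_that("transcript series sampling, noise and clipping", {
  tr <- data.frame(t = seq(0, 360, 15), S = 1, P = 1,
                   TDl = 1e5, TDm = 1e5, SL = 1, PL = 1,
                   TDlL = 2e5, TDmL = 2e5)
  s <- make_transcript_series(tr, schedule = 0:12, noise_cv = 0)
  expect_equal(s$bcr_abl_pct, rep(100 * 4e5 / (4e5 + 4e5), 13))
  # all-leukemic terminal compartments give 100%
  tr2 <- tr; tr2$TDl <- 0; tr2$TDm <- 0
  s2 <- make_transcript_series(tr2, schedule = 0:12)
  expect_equal(s2$bcr_abl_pct, rep(100, 13))
  expect_error(make_transcript_series(tr, schedule = 0:24), "span")
  # multiplicative lognormal noise with the requested CV
  set.seed(11)
  reps <- replicate(4000,
    make_transcript_series(tr, schedule = 0, noise_cv = 0.1)$bcr_abl_pct)
  cv <- sd(reps) / mean(reps)
  se_cv <- 0.1 / sqrt(2 * 4000)
  expect_lt(abs(cv - 0.1), 4 * se_cv)
})

test_that("cohort CSV round trip preserves parameters", {
  co <- fixture_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  df <- read.csv(path)
  expect_equal(nrow(df), length(co))
  prov <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(prov$seed, 7)
  if (length(co) > 0)
    expect_equal(df$p0_max, unname(co$params[, "p0_max"]))
})
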