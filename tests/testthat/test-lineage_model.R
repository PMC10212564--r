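test_that("evaluate_feedback returns maxima at zero regulators and halves
           at unit feedback", {
  ps <- fixture_params()
  r0 <- evaluate_feedback(ps, c(S = 0, P = 0, TDm = 0))
  expect_equal(unname(r0), unname(unclass(ps)[c("p0_max", "p1_max",
                                                "q1_max", "eta1_max",
                                                "eta2_max")]))
  # gamma1 * P = 1 halves p0
  P1 <- 1 / ps[["gamma1"]]
  r1 <- evaluate_feedback(ps, c(S = 0, P = P1, TDm = 0))
  expect_equal(r1[["p0"]], ps[["p0_max"]] / 2)
  # delta enters the p0 denominator only
  rd <- evaluate_feedback(ps, c(S = 0, P = 0, TDm = 0), delta = 1)
  expect_equal(rd[["p0"]], ps[["p0_max"]] / 2)
  expect_equal(rd[["p1"]], ps[["p1_max"]])
  expect_error(evaluate_feedback(ps, c(S = -1, P = 0, TDm = 0)),
               "non-negative")
  expect_error(evaluate_feedback(ps, c(S = 0, P = 0, TDm = 0), delta = -1),
               "non-negative")
})

test_that("each effective rate is strictly decreasing in its regulator", {
  ps <- fixture_params()
  grid <- 10^seq(2, 7, length.out = 12)
  p0 <- vapply(grid, function(P)
    evaluate_feedback(ps, c(S = 0, P = P, TDm = 0))[["p0"]], numeric(1))
  e1 <- vapply(grid, function(S)
    evaluate_feedback(ps, c(S = S, P = 0, TDm = 0))[["eta1"]], numeric(1))
  e2 <- vapply(grid, function(S)
    evaluate_feedback(ps, c(S = S, P = 0, TDm = 0))[["eta2"]], numeric(1))
  p1 <- vapply(grid, function(Tm)
    evaluate_feedback(ps, c(S = 0, P = 0, TDm = Tm))[["p1"]], numeric(1))
  q1 <- vapply(grid, function(Tm)
    evaluate_feedback(ps, c(S = 0, P = 0, TDm = Tm))[["q1"]], numeric(1))
  for (v in list(p0, e1, e2, p1, q1))
    expect_true(all(diff(v) < 0))
})

test_that("rhs_normal fixed-point structure", {
  ps <- fixture_params()
  expect_equal(unname(rhs_normal(c(S = 0, P = 0, TDl = 0, TDm = 0), ps)),
               rep(0, 4))
  # p0 = 1/2 exactly when gamma1 * P = 2 p0_max - 1
  P_half <- (2 * ps[["p0_max"]] - 1) / ps[["gamma1"]]
  d <- rhs_normal(c(S = 5e4, P = P_half, TDl = 0, TDm = 0), ps)
  expect_equal(d[["S"]], 0)
  expect_error(rhs_normal(c(S = -1, P = 0, TDl = 0, TDm = 0), ps),
               "non-negative")
})

test_that("feedback-free dynamics match the matrix-exponential oracle", {
  # vanishing gains put every denominator at 1 within double precision
  ps <- normal_parameter_set(p0_max = 0.7, p1_max = 0.4, q1_max = 0.3,
                             eta1_max = 0.05, eta2_max = 0.2, d_l = 0.05,
                             d_m = 0.3, gamma1 = 1e-30, gamma2 = 1e-30,
                             gamma3 = 1e-30, gamma4 = 1e-30,
                             gamma5 = 1e-30)
  p0 <- 0.7; p1 <- 0.4; q1 <- 0.3; e1 <- 0.05; e2 <- 0.2
  A <- matrix(c(
    (2 * p0 - 1) * e1, 0, 0, 0,
    2 * (1 - p0) * e1, (2 * p1 - 1) * e2, 0, 0,
    0, 2 * q1 * e2, -0.05, 0,
    0, 2 * (1 - p1 - q1) * e2, 0, -0.3), 4, 4, byrow = TRUE)
  y0 <- c(S = 200, P = 100, TDl = 50, TDm = 50)
  for (t1 in c(10, 60)) {
    num <- as.numeric(integrate_lineage(ps, y0, c(0, t1),
                                        atol = 1e-8)[2, -1])
    ana <- as.numeric(Matrix::expm(A * t1) %*% y0)
    expect_lt(max(abs(num - ana) / pmax(abs(ana), 1)), 1e-6)
  }
  # decoupled stem compartment grows as a pure exponential
  tr <- integrate_lineage(ps, c(S = 100, P = 0, TDl = 0, TDm = 0),
                          seq(0, 50, 10), atol = 1e-8)
  expect_equal(tr$S, 100 * exp((2 * p0 - 1) * e1 * tr$t), tolerance = 1e-7)
})

test_that("find_steady_state satisfies the closed-form identities", {
  ps <- fixture_params()
  st <- find_steady_state(ps)
  expect_true(st$converged)
  expect_lt(fixed_point_residual(ps, st$state), 1e-6)
  expect_equal(st$state[["P"]],
               (2 * ps[["p0_max"]] - 1) / ps[["gamma1"]],
               tolerance = 1e-6)
  # terminal-compartment balances
  r <- evaluate_feedback(ps, st$state[c("S", "P", "TDm")])
  expect_equal(st$state[["TDl"]],
               2 * r[["q1"]] * r[["eta2"]] * st$state[["P"]] / ps[["d_l"]],
               tolerance = 1e-6)
  # all-zero start stays extinct
  z <- find_steady_state(ps, c(S = 0, P = 0, TDl = 0, TDm = 0))
  expect_equal(unname(z$state), rep(0, 4))
  # the steady state is preserved under further integration
  tr <- integrate_lineage(ps, st$state, c(0, 200, 400))
  expect_lt(max(abs(as.numeric(tr[3, -1]) - st$state) / st$state), 1e-6)
})

test_that("myeloid depletion recovers monotonically to the same
           equilibrium", {
  ps <- reference_patient()
  eq <- find_steady_state(ps)$state
  for (f in c(0.1, 0.5, 0.9)) {
    y0 <- eq; y0["TDm"] <- y0["TDm"] * (1 - f)
    tr <- integrate_lineage(ps, y0, seq(0, 400, 1))
    expect_lt(abs(tr$TDm[nrow(tr)] - eq[["TDm"]]) / eq[["TDm"]], 0.01)
    # near-monotone recovery: the myeloid compartment climbs back with at
    # most a modest damped-oscillation overshoot
    expect_true(all(diff(tr$TDm) > -0.1 * eq[["TDm"]]))
    expect_gt(max(tr$TDm), tr$TDm[1])
  }
})

test_that("populations stay non-negative for random parameter draws", {
  set.seed(71)
  draws <- sample_parameters(12, enriched_sampling_ranges())
  for (i in seq_len(nrow(draws))) {
    ps <- hemopoiesis:::params_from_vector(draws[i, ])
    tr <- integrate_lineage(ps, c(S = 1e3, P = 0, TDl = 0, TDm = 0),
                            seq(0, 2000, 20))
    expect_true(all(as.matrix(tr[, -1]) >= 0))
  }
})
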