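test_that("dual system reduces to the single lineage when leukemia is
           absent", {
  ps <- fixture_params()
  dual <- dual_parameter_set(ps, gamma1L_ratio = 0.5)
  st <- c(S = 2e4, P = 1e5, TDl = 3e5, TDm = 4e5)
  d <- rhs_dual(c(st, SL = 0, PL = 0, TDlL = 0, TDmL = 0), dual)
  expect_equal(unname(d[5:8]), rep(0, 4))
  expect_equal(d[1:4], rhs_normal(st, ps))
})

test_that("label-linearity: identically parameterized sub-lineages evolve
           as the merged system", {
  ps <- fixture_params()
  dual <- dual_parameter_set(ps, gamma1L_ratio = 1, p0_maxL_ratio = 1)
  eq <- find_steady_state(ps)$state
  # split each compartment 70/30 between the two labels
  y0 <- c(eq * 0.7, eq * 0.3)
  names(y0) <- c("S", "P", "TDl", "TDm", "SL", "PL", "TDlL", "TDmL")
  times <- seq(0, 500, 25)
  tr <- hemopoiesis:::integrate_dual(y0, dual, times, rtol = 1e-10, atol = 1e-8)
  merged <- integrate_lineage(ps, eq, times, rtol = 1e-10, atol = 1e-8)
  tot <- as.matrix(tr[, 2:5]) + as.matrix(tr[, 6:9])
  expect_lt(max(abs(tot - as.matrix(merged[, -1])) /
                  pmax(as.matrix(merged[, -1]), 1)), 1e-8)
  # also from a perturbed (off-equilibrium) split state
  y1 <- y0; y1["P"] <- y1["P"] * 2; y1["PL"] <- y1["PL"] * 0.5
  tr1 <- hemopoiesis:::integrate_dual(y1, dual, times, rtol = 1e-10, atol = 1e-8)
  m1 <- integrate_lineage(ps, y1[1:4] + y1[5:8], times, rtol = 1e-10, atol = 1e-8)
  tot1 <- as.matrix(tr1[, 2:5]) + as.matrix(tr1[, 6:9])
  expect_lt(max(abs(tot1 - as.matrix(m1[, -1])) /
                  pmax(as.matrix(m1[, -1]), 1)), 1e-8)
})

test_that("weaker leukemic feedback drives takeover", {
  dual <- reference_dual(gamma1L_ratio = 0.5)
  tr <- simulate_cml(dual, t_span = 2000, dt_out = 10)
  # leukemic fractions increase monotonically toward 1 in each compartment
  for (fr in list(tr$frac_S, tr$frac_P, tr$frac_TD)) {
    expect_true(all(diff(fr) > -1e-6))
    expect_gt(fr[length(fr)], 0.99)
  }
  # no seed, no leukemia
  tr0 <- simulate_cml(dual, n_seed_LSC = 0, t_span = 300, dt_out = 50)
  expect_true(all(tr0$SL == 0))
  eq <- find_steady_state(dual$normal)$state
  expect_lt(max(abs(as.numeric(tr0[nrow(tr0), 2:5]) - eq) / eq), 1e-4)
})

test_that("the all-leukemic end state satisfies the leukemic fixed-point
           identities", {
  dual <- reference_dual(gamma1L_ratio = 0.5)
  tr <- simulate_cml(dual, t_span = 6000, dt_out = 100)
  end <- tr[nrow(tr), ]
  expect_gt(end$frac_TD, 0.999)
  lk <- dual$leukemic
  expect_equal(end$PL, (2 * lk[["p0_max"]] - 1) / lk[["gamma1"]],
               tolerance = 1e-3)
})

test_that("fitness ratio arithmetic and constructor guards", {
  ps <- fixture_params()
  expect_equal(fitness(dual_parameter_set(ps, gamma1L_ratio = 1)), 1)
  # gamma1 * N = 1, halving the leukemic gain gives (1+1)/(1+0.5) = 4/3
  ps2 <- unclass(ps); ps2[["gamma1"]] <- 1e-5
  ps2 <- hemopoiesis:::params_from_vector(ps2)
  expect_equal(fitness(dual_parameter_set(ps2, gamma1L_ratio = 0.5),
                       N_char = 1e5), 4 / 3)
  expect_error(dual_parameter_set(ps, p0_maxL_ratio = 1.2),
               "p0_maxL_ratio")
  expect_error(dual_parameter_set(fixture_params(), p0_maxL_ratio = 0.5),
               "0.5")
})

test_that("takeover map is monotone in the leukemic feedback advantage", {
  co <- fixture_cohort()
  expect_gte(length(co), 2)
  sw <- sweep_leukemic_parameters(co,
                                  p0maxL_ratio_grid = 1,
                                  gamma1L_ratio_grid = c(0.1, 0.3, 0.6),
                                  horizon = 2500)
  # takeover proportion non-increasing in gamma1L/gamma1
  expect_true(all(diff(sw$fraction_takeover) <= 1e-12))
  # strongest-advantage corner takes over in (nearly) all members
  expect_gte(sw$fraction_takeover[1], 0.9)
  # fitness decreases with gamma1L ratio, takeover tracks fitness
  expect_true(all(diff(sw$mean_fitness) < 0))
})
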