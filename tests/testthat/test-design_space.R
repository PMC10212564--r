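test_that("enumeration counts match the combinatorial identities", {
  expect_equal(nrow(enumerate_schemes()), 9^5)          # 59049
  expect_equal(nrow(enumerate_schemes(list(p0 = "negative"))), 4 * 9^4)
  expect_equal(nrow(enumerate_schemes(
    list(p0 = "P-", q1 = "TDm-"))), 9^3)                # 729
  expect_equal(nrow(enumerate_schemes(
    list(p0 = c("P-", "S-"), eta2 = "none"))), 2 * 9^3)
  expect_error(enumerate_schemes(list(p0 = integer(0))), "constraint")
  expect_error(enumerate_schemes(list(bogus = "P-")), "unknown")
})

test_that("subsystem counts follow the source/sink/regime bookkeeping", {
  # fully unregulated: the stem equation has no sink, nothing can balance
  expect_length(build_ssystems(regulation_scheme()), 0)
  # p0 <- P negative only: 2 denominator branches x (1 src x 1 snk) for S,
  # (2 src x 1 snk) for P (p1-low sign regime only; the high regime has no
  # P sink), 1 x 1 for TDl, 1 x 1 for TDm
  expect_length(build_ssystems(regulation_scheme(p0 = "P-")), 4)
  # the selected architecture: per branch assignment (2^5), low p1 regime
  # gives 2x2x1x4 = 16 combos, high gives 3x1x1x4 = 12
  expect_length(build_ssystems(fig2f_scheme()), 32 * 28)
})

test_that("solved subsystems balance their dominant terms exactly and
           match a brute-force root", {
  theta <- hemopoiesis:::theta_from_params(reference_patient())
  sss <- build_ssystems(fig2f_scheme())
  solved <- 0
  for (ss in sss) {
    eq <- solve_ssystem(ss, theta)
    if (is.null(eq)) next
    solved <- solved + 1
    lt <- log(as.numeric(theta))
    clog <- hemopoiesis:::coef_logs(as.numeric(theta))
    y <- log(as.numeric(eq))
    bal <- vapply(ss$balance, hemopoiesis:::expr_val, numeric(1),
                  lt = lt, clog = clog, y = y)
    # at the equilibrium every log(sink) - log(source) vanishes
    expect_lt(max(abs(bal)), 1e-10)
    if (solved == 1) {
      # independent oracle: minimize the squared balance residuals
      bal0 <- function(yy) vapply(ss$balance, hemopoiesis:::expr_val,
                                  numeric(1), lt = lt, clog = clog,
                                  y = yy)
      f <- function(yy) sum(bal0(yy)^2)
      fit <- optim(y + 0.5, f, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      expect_lt(max(abs(fit$par - y)), 1e-4)
    }
  }
  expect_gt(solved, 0)
})

test_that("consistency flags fail when a regime inequality is violated", {
  theta <- hemopoiesis:::theta_from_params(reference_patient())
  sss <- build_ssystems(fig2f_scheme())
  found <- FALSE
  for (ss in sss) {
    eq <- solve_ssystem(ss, theta)
    if (is.null(eq)) next
    v <- check_consistency_and_stability(ss, eq, theta)
    if (v[["consistent"]]) {
      found <- TRUE
      # shrink the p0 gain a million-fold: its high-branch regime
      # requirement gamma * P > 1 must now fail at the same equilibrium
      th2 <- theta
      if (any(ss$branch == 1L)) {
        q <- which(ss$branch == 1L)[1]
        th2[7 + q] <- th2[7 + q] * 1e-6
        eq2 <- solve_ssystem(ss, th2)
        if (!is.null(eq2)) {
          v2 <- check_consistency_and_stability(ss, eq2, th2)
          expect_false(v2[["consistent"]] && v2[["stable"]] &&
                         all(v[c("consistent", "stable")]) &&
                         identical(eq, eq2))
        }
      }
      break
    }
  }
  expect_true(found)
})

test_that("compiled and reference screens agree on a random scheme
           sample", {
  set.seed(99)
  sch <- enumerate_schemes()
  idx <- sample(nrow(sch), 25)
  lt <- dsa_parameter_sample(8, seed = 3)
  cpp <- hemopoiesis:::cpp_dsa_screen(sch[idx, , drop = FALSE], lt)
  for (k in seq_along(idx)) {
    scheme <- structure(sch[idx[k], ], class = "regulation_scheme")
    rres <- hemopoiesis:::screen_scheme_r(scheme, lt)
    expect_identical(rres$accepted, cpp$accepted[k])
    expect_identical(rres$n_surviving, cpp$n_surviving[k])
  }
})

test_that("surviving subsystems are confirmed stable by integrating the
           full Hill model at the witness point", {
  set.seed(17)
  sch <- enumerate_schemes(list(p0 = "negative"))
  idx <- sample(nrow(sch), 40)
  lt <- dsa_parameter_sample(8, seed = 3)
  confirmed <- 0
  for (k in idx) {
    if (confirmed >= 6) break
    code <- as.integer(sch[k, ])
    hit <- NULL
    for (r in seq_len(nrow(lt))) {
      d <- hemopoiesis:::cpp_dsa_detail(code, lt[r, ])
      ok <- which(d$pass == 1)
      if (length(ok)) { hit <- d[ok[1], ]; theta <- exp(lt[r, ]); break }
    }
    if (is.null(hit)) next
    eq <- as.numeric(hit[c("S", "P", "TDl", "TDm")])
    rhs <- function(y) hill_rhs_scheme(code, theta, y)
    rate <- max(abs(rhs(eq)) / (eq + 1))
    y <- rk4(rhs, eq * c(1.03, 0.97, 1.02, 0.98), 30 / max(rate, 1e-4),
             0.05 / max(rate, 1e-4))
    if (any(is.na(y))) next
    # the trajectory stays in the neighborhood of the subsystem
    # equilibrium (dominance is an approximation, so allow a loose band)
    expect_true(all(y > eq / 25 & y < eq * 25))
    confirmed <- confirmed + 1
  }
  expect_gte(confirmed, 3)
})

test_that("targeted screens reproduce the class structure", {
  lt <- dsa_parameter_sample(16, seed = 1)
  expect_true(filter_models(fig2f_scheme(), lt)$verdicts$accepted)
  for (src in c("S-", "P-", "TDl-", "TDm-")) {
    v <- filter_models(do.call(regulation_scheme, list(p0 = src)),
                       lt)$verdicts
    expect_true(v$accepted)
    expect_equal(v$p0_negative_source, sub("-", "", src))
  }
  # no p0 regulation or positive p0 regulation: never accepted
  set.seed(5)
  none <- enumerate_schemes(list(p0 = "none"))
  pos <- enumerate_schemes(list(p0 = "positive"))
  sub <- rbind(none[sample(nrow(none), 15), ], pos[sample(nrow(pos), 15), ])
  res <- hemopoiesis:::cpp_dsa_screen(sub, lt)
  expect_false(any(res$accepted))
})

test_that("design-space map labels regions and node/spiral types", {
  ps <- reference_patient()
  g1 <- unclass(ps)[["gamma1"]] * c(0.5, 1, 2)
  g3 <- unclass(ps)[["gamma3"]] * c(0.5, 1, 2)
  m <- map_design_space(ps, g1, g3)
  expect_equal(nrow(m), 9)
  # labels exist wherever the steady state converged; region 0 marks
  # boundary points where no regime holds strictly
  conv <- !is.na(m$region)
  expect_gt(sum(conv), 5)
  expect_true(all(m$type[conv] %in% c("node", "spiral")))
  # pick an interior point (nonzero region) and check label stability
  # under a +/-10% gain perturbation
  interior <- m[conv & m$region > 0, ][1, ]
  mp <- map_design_space(ps, interior$gamma1 * c(0.9, 1.1),
                         interior$gamma3 * c(0.9, 1.1))
  expect_true(all(mp$region == interior$region, na.rm = TRUE))
  expect_true(all(mp$type == interior$type, na.rm = TRUE))
  # spiral/node label matches the oscillation signature of the approach
  # to equilibrium from a small perturbation (at the reference gains)
  center <- m[m$gamma1 == g1[2] & m$gamma3 == g3[2], ]
  eq <- find_steady_state(ps)$state
  tr <- integrate_lineage(ps, eq * c(1.2, 1, 1, 1), seq(0, 3000, 2))
  sgn <- sign(tr$S - eq[["S"]])
  crossings <- sum(diff(sgn[sgn != 0]) != 0)
  # oscillatory approach implies a spiral label (the converse may be
  # unobservable when the rotation period exceeds the horizon)
  expect_true(crossings < 2 || center$type == "spiral")
})
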