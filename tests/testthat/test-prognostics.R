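test_that("PF relative change arithmetic and invariances", {
  expect_equal(pf_relative_change(5, 5), 0)
  expect_equal(pf_relative_change(10, 2), -4)
  expect_lt(pf_relative_change(10, 2), -3.2)   # responder side of the clinical cut
  expect_equal(pf_relative_change(10, 2), pf_relative_change(30, 6))
  expect_identical(pf_relative_change(10, 0), -Inf)
  expect_error(pf_relative_change(-1, 2))
})

test_that("halving time formula and sentinels", {
  s <- fixture_series(c(100, 80, 60, 40, 30, 25, 20), months = 0:6)
  expect_equal(halving_time(s, c(3, 6)), 3 * log(2) / log(2))
  s2 <- fixture_series(c(100, 100, 100, 100), months = c(0, 3, 6, 9))
  expect_identical(halving_time(s2, c(3, 6)), Inf)
  s3 <- fixture_series(c(100, 50, 25, 12.5), months = 0:3)
  expect_equal(halving_time(s3, c(0, 3)), 1)
  expect_error(halving_time(fixture_series(c(0, 1), months = c(3, 6)),
                            c(3, 6)), "undefined")
})

test_that("early molecular response uses strict thresholds", {
  mk <- function(b3, b6) fixture_series(c(50, 30, 20, b3, 15, 10, b6),
                                        months = 0:6)
  expect_identical(emr(mk(9.9, 0.5)), c(EMR3 = TRUE, EMR6 = TRUE))
  expect_identical(emr(mk(10, 1)), c(EMR3 = FALSE, EMR6 = FALSE))
  expect_error(emr(fixture_series(c(1, 2), months = c(0, 1))), "cover")
})

test_that("ROC evaluation: separation, null behavior, invariance", {
  scores <- c(-5, -4, -3.5, -0.2, 0.1, 0.5)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_evaluate(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_true(all(r$tpr >= 0 & r$tpr <= 1 & r$fpr >= 0 & r$fpr <= 1))
  # Youden optimum invariant under monotone transforms of the scores
  r2 <- roc_evaluate(qnorm(pnorm(scores)) * 3 + 1, labels)
  expect_equal(r2$sensitivity, r$sensitivity)
  expect_equal(r2$specificity, r$specificity)
  expect_error(roc_evaluate(scores, rep(TRUE, 6)), "both")
  # permutation null: AUC concentrates near 1/2
  set.seed(41)
  aucs <- replicate(200, {
    sc <- rnorm(40)
    roc_evaluate(sc, sample(rep(c(TRUE, FALSE), 20)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("compare_windows depends on window endpoints only for PF", {
  a <- fixture_series(c(80, 40, 20, 10, 5, 2, 1), months = 0:6)
  b <- a; b$bcr_abl_pct[c(2, 3, 6)] <- c(70, 60, 3)  # same 0/3/6 values
  c1 <- fixture_series(c(90, 80, 70, 60, 55, 50, 45), months = 0:6)
  labels <- c(TRUE, FALSE)
  out_a <- compare_windows(list(a, c1), labels)
  out_b <- compare_windows(list(b, c1), labels)
  pf <- function(o) o[o$statistic == "PF", ]
  expect_equal(pf(out_a), pf(out_b))
})

test_that("transcript CSV ingestion snaps visits and drops incomplete
           patients", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(
    patient_id = c(rep("A", 4), rep("B", 3)),
    month = c(0, 3.2, 5.8, 9, 0, 3, 9),      # B misses month 6
    bcr_abl_pct = c(60, 12, 3, 0.5, 70, 20, 5))
  write.csv(df, path, row.names = FALSE)
  res <- read_transcript_csv(path)
  expect_named(res, "A")
  expect_identical(attr(res, "dropped"), "B")
  expect_equal(res$A$month, c(0, 3, 6, 9))
  expect_equal(res$A$bcr_abl_pct[3], 3)
})
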