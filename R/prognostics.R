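#' Relative-change prognostic statistic
#'
#' `PF = (B(end) - B(start)) / B(end)` on transcript percentages; strongly
#' negative values indicate a steep relative decline. With `B(end) = 0`
#' (a perfect responder) the score is `-Inf`, which sorts as most
#' responsive.
#'
#' @param b_start,b_end transcript percentages at the window endpoints.
#' @return The PF score (dimensionless; `-Inf` when `b_end` is 0).
#' @export
pf_relative_change <- function(b_start, b_end) {
  stopifnot(b_start >= 0, b_end >= 0)
  if (b_end == 0) return(-Inf)
  (b_end - b_start) / b_end
}

#' Transcript halving time
#'
#' `t_half = (t2 - t1) log 2 / log(B(t1) / B(t2))` over a window; a
#' non-declining series gets `+Inf` (no halving).
#'
#' @param series a `transcript_series` data frame.
#' @param window months `c(t1, t2)`; both must be scheduled visits.
#' @return Halving time in months (`+Inf` when not declining).
#' @export
halving_time <- function(series, window = c(3, 6)) {
  b <- series_at(series, window)
  if (any(b <= 0)) stop("halving time undefined for non-positive values")
  if (b[2] >= b[1]) return(Inf)
  (window[2] - window[1]) * log(2) / log(b[1] / b[2])
}

series_at <- function(series, months) {
  idx <- match(months, series$month)
  if (any(is.na(idx)))
    stop("series does not cover months ", paste(months, collapse = ", "))
  series$bcr_abl_pct[idx]
}

#' Early molecular response verdicts
#'
#' EMR3: transcript < 10% at month 3; EMR6: transcript < 1% at month 6
#' (strict inequalities).
#'
#' @param series a `transcript_series` data frame covering months 3 and 6.
#' @return Named logical vector `EMR3, EMR6`.
#' @export
emr <- function(series) {
  b <- series_at(series, c(3, 6))
  c(EMR3 = b[1] < 10, EMR6 = b[2] < 1)
}

#' ROC evaluation of a prognostic score
#'
#' Lower scores are treated as more responsive (positive class). The
#' full threshold sweep is returned together with the Youden-optimal
#' operating point (`J = TPR - FPR`, ties broken toward higher
#' specificity).
#'
#' @param scores numeric scores, one per patient.
#' @param labels logical responder labels.
#' @return List of class `roc_result`: `thresholds, tpr, fpr, auc,
#'   optimal_threshold, sensitivity, specificity`.
#' @export
roc_evaluate <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("need both responders and non-responders")
  np <- sum(labels); nn <- sum(!labels)
  # predict positive when score <= threshold
  thr <- c(-Inf, sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) sum(scores[labels] <= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] <= t) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(fpr[best])]   # ties toward higher specificity
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 optimal_threshold = thr[best], sensitivity = tpr[best],
                 specificity = 1 - fpr[best]), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.3f; optimal threshold %.3g ",
                     "(sens %.3f, spec %.3f)\n"),
              x$auc, x$optimal_threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Compare prognostic statistics across scoring windows
#'
#' Evaluates PF, halving time and EMR on the 0-3 and 3-6 month windows of
#' each series and returns sensitivity, specificity and AUC per
#' (statistic, window).
#'
#' @param series_list list of `transcript_series` covering months 0-6.
#' @param labels logical responder labels, one per series.
#' @return Data frame `statistic, window, sensitivity, specificity, auc,
#'   optimal_threshold`.
#' @export
compare_windows <- function(series_list, labels) {
  stopifnot(length(series_list) == length(labels))
  floor_pct <- 1e-6    # measurement floor avoids log(0) in halving times
  get <- function(s, m) max(series_at(s, m), floor_pct)
  rows <- list()
  for (w in list(c(0, 3), c(3, 6))) {
    pf <- vapply(series_list, function(s)
      pf_relative_change(get(s, w[1]), get(s, w[2])), numeric(1))
    ht <- vapply(series_list, function(s) {
      b <- c(get(s, w[1]), get(s, w[2]))
      if (b[2] >= b[1]) Inf else diff(w) * log(2) / log(b[1] / b[2])
    }, numeric(1))
    # EMR as a score: the transcript level at the window end, against the
    # clinical cutoffs 10% (month 3) and 1% (month 6)
    em <- vapply(series_list, function(s) get(s, w[2]), numeric(1))
    for (stat in c("PF", "halving_time", "EMR")) {
      sc <- switch(stat, PF = pf, halving_time = ht, EMR = em)
      r <- roc_evaluate(sc, labels)
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = stat, window = paste(w, collapse = "-"),
        sensitivity = r$sensitivity, specificity = r$specificity,
        auc = r$auc, optimal_threshold = r$optimal_threshold)
    }
  }
  do.call(rbind, rows)
}

#' Read clinic transcript series from CSV
#'
#' Expects columns `patient_id, month, bcr_abl_pct`. Months are snapped
#' to the nearest scheduled monthly visit within 0.5 month; patients
#' missing the 3- or 6-month visit are dropped (and reported).
#'
#' @param path CSV path.
#' @return Named list of `transcript_series`, one per retained patient,
#'   with attribute `dropped` naming excluded patients.
#' @export
read_transcript_csv <- function(path) {
  df <- read.csv(path)
  need <- c("patient_id", "month", "bcr_abl_pct")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ", "))
  df <- df[complete.cases(df[, need]), need]
  df$visit <- round(df$month)
  df <- df[abs(df$month - df$visit) <= 0.5, ]
  out <- list(); dropped <- character(0)
  for (pid in unique(df$patient_id)) {
    d <- df[df$patient_id == pid, ]
    d <- d[!duplicated(d$visit), ]
    if (!all(c(3, 6) %in% d$visit)) {
      dropped <- c(dropped, as.character(pid)); next
    }
    d <- d[order(d$visit), ]
    out[[as.character(pid)]] <- structure(
      data.frame(patient_id = pid, month = d$visit,
                 bcr_abl_pct = pmin(pmax(d$bcr_abl_pct, 0), 100)),
      class = c("transcript_series", "data.frame"))
  }
  attr(out, "dropped") <- dropped
  out
}
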