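#' Day-level confusion metrics
#'
#' Precision, recall, balanced accuracy (mean of sensitivity and
#' specificity -- the tuning objective) and false positive rate for a set
#' of predicted vs true daily presence labels. Undefined ratios (empty
#' denominators) are returned as `NA`.
#'
#' @param pred,truth logical vectors of equal length.
#' @return object of class `confusion_report`: list with `tp`, `fp`, `tn`,
#'   `fn`, `precision`, `recall`, `balanced_accuracy`, `fpr`.
#' @export
confusion_metrics <- function(pred, truth) {
  .assert(length(pred) == length(truth), "pred and truth must have equal length")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- ratio(tp, tp + fn)
  specificity <- ratio(tn, tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = ratio(tp, tp + fp),
                 recall = recall,
                 balanced_accuracy = mean(c(recall, specificity)),
                 fpr = ratio(fp, fp + tn)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d | precision=%.3f recall=%.3f balanced_acc=%.3f fpr=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$precision, x$recall,
              x$balanced_accuracy, x$fpr))
  invisible(x)
}

#' Tune the repetition threshold r against a labeled corpus
#'
#' Runs the full detection chain once per day (candidates are detected a
#' single time; the interval filter is then re-applied for every `r` in
#' the grid) and scores each `r` by day-level balanced accuracy against
#' the corpus truth labels. Ties are broken toward the larger, more
#' conservative `r`.
#'
#' @param corpus list of `labeled_day` objects ([gen_labeled_corpus()]),
#'   with at least one positive and one negative day.
#' @param cfg a [detector_config()].
#' @param r_grid candidate repetition thresholds.
#' @param progress print per-day progress to stderr.
#' @return list with `best_r`, `reports` (one data.frame row per `r`) and
#'   `predictions` (day x r logical matrix).
#' @export
tune_r <- function(corpus, cfg = detector_config(), r_grid = 3:10,
                   progress = FALSE) {
  .assert(length(corpus) >= 2, "corpus must contain at least two days")
  truth <- vapply(corpus, function(d) isTRUE(d$truth_present), logical(1))
  .assert(any(truth) && any(!truth),
          "degenerate corpus: need at least one positive and one negative day")
  .assert(all(r_grid >= 1), "r_grid values must be >= 1")

  detection_times <- lapply(seq_along(corpus), function(i) {
    day <- materialize_day(corpus[[i]])
    env <- band_energy_envelope(day$waveform, day$fs, cfg)
    cand <- detect_candidates(env, cfg)
    if (progress) message(sprintf("  day %d/%d: %d candidates", i, length(corpus), nrow(cand)))
    cand$time
  })

  pred <- vapply(r_grid, function(r) {
    vapply(detection_times, function(times) {
      nrow(find_click_sequences(times, r = r)) > 0
    }, logical(1))
  }, logical(length(corpus)))
  colnames(pred) <- as.character(r_grid)

  reports <- do.call(rbind, lapply(seq_along(r_grid), function(j) {
    cm <- confusion_metrics(pred[, j], truth)
    data.frame(r = r_grid[j], tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
               precision = cm$precision, recall = cm$recall,
               balanced_accuracy = cm$balanced_accuracy, fpr = cm$fpr)
  }))
  best <- max(reports$balanced_accuracy, na.rm = TRUE)
  best_r <- max(reports$r[which(reports$balanced_accuracy == best)])
  list(best_r = best_r, reports = reports, predictions = pred, truth = truth)
}
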