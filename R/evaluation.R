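#' Patient-hour AUROC (c-statistic)
#'
#' Probability that a randomly chosen positive patient-hour outscores a
#' randomly chosen negative one, ties counted one half; computed pooled
#' over all rows via the rank statistic.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`, or `NA` (with a warning) if one class is
#'   absent.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUROC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Patient-level bootstrap confidence interval
#'
#' Resamples patients (not rows) with replacement, recomputes the metric on
#' the concatenated rows of the resampled patients, and returns the 2.5 and
#' 97.5 percentile of the resample distribution. Resamples on which the
#' metric is undefined (`NA`) are redrawn; the redraw count is recorded in
#' the `"n_redrawn"` attribute.
#'
#' @param metric_fn `function(scores, labels) -> numeric`.
#' @param scores,labels Patient-hour scores and labels.
#' @param stay_ids Stay identifier per row (the resampling unit).
#' @param n_resamples Number of bootstrap resamples (default 100).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @param conf Confidence level (default 0.95).
#' @return `c(lower, upper)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, stay_ids,
                         n_resamples = 100, seed = 1L, conf = 0.95) {
  ids <- unique(stay_ids)
  if (length(ids) < 2L) stopf("bootstrap_ci needs at least 2 patients")
  by_stay <- split(seq_along(stay_ids), stay_ids)
  stats <- numeric(n_resamples)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      repeat {
        pick <- sample(ids, length(ids), replace = TRUE)
        rows <- unlist(by_stay[as.character(pick)], use.names = FALSE)
        val <- suppressWarnings(metric_fn(scores[rows], labels[rows]))
        if (!is.na(val)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 50L * n_resamples)
          stopf("bootstrap metric undefined in too many resamples")
      }
      stats[b] <- val
    }
  })
  a <- (1 - conf) / 2
  out <- unname(quantile(stats, c(a, 1 - a), type = 7))
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Sensitivity, specificity and accuracy of binary predictions
#'
#' @param predictions 0/1 (or logical) predicted labels per patient-hour.
#' @param labels 0/1 true labels.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(predictions, labels) {
  predictions <- as.integer(as.logical(predictions))
  tp <- sum(predictions == 1 & labels == 1)
  fn <- sum(predictions == 0 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels))
}

#' ROC curve point set
#'
#' Sensitivity/1-specificity pairs over the distinct score thresholds
#' (subsampled to at most `max_points`).
#'
#' @param scores,labels Scores and 0/1 labels.
#' @param max_points Maximum number of returned points.
#' @return `data.table` (`threshold`, `fpr`, `tpr`).
#' @export
roc_points <- function(scores, labels, max_points = 200L) {
  thr <- sort(unique(scores), decreasing = TRUE)
  if (length(thr) > max_points)
    thr <- thr[unique(round(seq(1, length(thr), length.out = max_points)))]
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  data.table(threshold = thr,
             fpr = vapply(thr, function(s) sum(scores >= s & labels == 0) / neg,
                          numeric(1)),
             tpr = vapply(thr, function(s) sum(scores >= s & labels == 1) / pos,
                          numeric(1)))
}
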