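#' Binary classification metrics
#'
#' Accuracy, recall, precision, F1 and AUC-ROC for a binary task with
#' positive class 1. When `scores` are supplied the AUC is the
#' Mann-Whitney rank statistic (ties counted half); otherwise it is the
#' balanced accuracy `(TPR + TNR) / 2` of the single hard-label
#' operating point. Ratios with a zero denominator are reported as 0 and
#' flagged in `degenerate`.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @param scores Optional numeric scores (higher means more positive).
#' @return A one-row tibble: `accuracy`, `recall`, `precision`, `f1`,
#'   `auc_roc`, the confusion counts `tp`, `fp`, `tn`, `fn`, and a
#'   `degenerate` flag marking division-by-zero fallbacks.
#' @examples
#' evaluate_classifier(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
evaluate_classifier <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` differ in length.", call. = FALSE)
  }
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("Labels must be binary (0/1).", call. = FALSE)
  }
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  S <- length(y_true)
  degenerate <- FALSE
  safe_ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; return(0) }
    num / den
  }
  recall <- safe_ratio(tp, tp + fn)
  precision <- safe_ratio(tp, tp + fp)
  f1 <- safe_ratio(2 * precision * recall, precision + recall)
  if (is.null(scores)) {
    tpr <- safe_ratio(tp, tp + fn)
    tnr <- safe_ratio(tn, tn + fp)
    auc <- (tpr + tnr) / 2
  } else {
    auc <- rank_auc(y_true, scores)
    if (is.na(auc)) { degenerate <- TRUE; auc <- 0 }
  }
  tibble::tibble(
    accuracy = (tp + tn) / S, recall = recall, precision = precision,
    f1 = f1, auc_roc = auc,
    tp = tp, fp = fp, tn = tn, fn = fn,
    degenerate = degenerate
  )
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(equal).
rank_auc <- function(y_true, scores) {
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Median with a bootstrap percentile confidence interval
#'
#' @param values Nonempty numeric vector.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return A one-row tibble: `median`, `lower`, `upper`, `n`.
#' @export
median_with_ci <- function(values, level = 0.95, n_boot = 2000L, seed = 1L) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("`values` must be nonempty and NA-free.", call. = FALSE)
  }
  med <- stats::median(values)
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(median = med, lower = med, upper = med,
                          n = length(values)))
  }
  withr::local_seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(values, replace = TRUE))
  }, double(1))
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  tibble::tibble(median = med, lower = qs[1], upper = qs[2],
                 n = length(values))
}
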