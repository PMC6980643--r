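# Shared metrics, cross-validation machinery and the printed-table
# consistency calculator.

#' Round half away from zero
#'
#' Plain decimal rounding with ties going up, matching how the published
#' tables this package mirrors render percentages. Base `round()` rounds
#' half to even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.pct <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * x, digits))
}

#' Build an evaluation report from confusion counts
#'
#' Sensitivity is the probability of identifying the positive class
#' (an edible-oil-related item, or a problematic B manufacturer);
#' specificity the probability of identifying the negative class.
#' All rates are stored as proportions and rendered as percentages to
#' two decimals by the print method.
#'
#' @param TP,FN,TN,FP non-negative integer confusion counts.
#'   `TP + FN` is the number of positive-class records, `TN + FP` the
#'   number of negative-class records; both must be positive.
#' @param method optional character tag recording which classifier
#'   produced the counts.
#' @param seed optional integer recording the seed that produced them.
#' @return an object of class `eval_report`: a list with `sensitivity`,
#'   `specificity`, `error_rate` (proportions), the four counts,
#'   `n_pos`, `n_neg`, `method` and `seed`.
#' @examples
#' metrics_from_confusion(TP = 19, FN = 8, TN = 423, FP = 2)
#' @export
metrics_from_confusion <- function(TP, FN, TN, FP,
                                   method = NA_character_,
                                   seed = NA_integer_) {
  TP <- unname(TP); FN <- unname(FN); TN <- unname(TN); FP <- unname(FP)
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("confusion counts must be non-negative integers")
  n_pos <- TP + FN
  n_neg <- TN + FP
  if (n_pos == 0) stop("no positive-class records (TP + FN = 0)")
  if (n_neg == 0) stop("no negative-class records (TN + FP = 0)")
  structure(
    list(sensitivity = TP / n_pos,
         specificity = TN / n_neg,
         error_rate  = (FN + FP) / (n_pos + n_neg),
         TP = TP, FN = FN, TN = TN, FP = FP,
         n_pos = n_pos, n_neg = n_neg,
         method = method, seed = seed),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report",
      if (!is.na(x$method)) paste0("(", x$method, ")"), "\n")
  cat(sprintf("  sensitivity: %s  (%d/%d)\n",
              .pct(x$sensitivity), x$TP, x$n_pos))
  cat(sprintf("  specificity: %s  (%d/%d)\n",
              .pct(x$specificity), x$TN, x$n_neg))
  cat(sprintf("  error rate:  %s  (%d/%d)\n",
              .pct(x$error_rate), x$FN + x$FP, x$n_pos + x$n_neg))
  invisible(x)
}

#' Confusion counts from truth and prediction vectors
#'
#' @param truth,pred vectors of equal length (factor or character).
#' @param positive the label counted as the positive class.
#' @return named integer vector with `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == positive & pred == positive),
    FN = sum(truth == positive & pred != positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive))
}

#' Evaluation report directly from predictions
#'
#' @inheritParams confusion_counts
#' @inheritParams metrics_from_confusion
#' @return an `eval_report`; see [metrics_from_confusion()].
#' @export
evaluate_predictions <- function(truth, pred, positive,
                                 method = NA_character_, seed = NA_integer_) {
  cc <- confusion_counts(truth, pred, positive)
  metrics_from_confusion(cc["TP"], cc["FN"], cc["TN"], cc["FP"],
                         method = method, seed = seed)
}

#' Error rate implied by printed sensitivity and specificity
#'
#' Published performance tables often print sensitivity, specificity and
#' an overall error rate without the underlying confusion matrix. Given
#' the class sizes, the error counts can be recovered: the number of
#' false negatives is the nearest integer to `(1 - sensitivity) * n_pos`
#' and the false positives the nearest integer to
#' `(1 - specificity) * n_neg`. The implied overall error rate is their
#' sum over the total, and serves as an internal-consistency check on
#' such tables.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @param n_pos,n_neg positive integer class sizes.
#' @return implied error rate as a proportion.
#' @examples
#' # a linear SVM that never flags the positive class, with 27 positives
#' # out of 452 records, implies an error rate of 27/452 = 5.97%
#' implied_error_rate(0, 1, 27, 425)
#' @export
implied_error_rate <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop("sensitivity and specificity must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1 || n_pos != floor(n_pos) || n_neg != floor(n_neg))
    stop("n_pos and n_neg must be positive integers")
  FN <- floor((1 - sensitivity) * n_pos + 0.5)
  FP <- floor((1 - specificity) * n_neg + 0.5)
  (FN + FP) / (n_pos + n_neg)
}

#' Stratified cross-validation folds
#'
#' Assigns each record to one of `k` folds such that folds are disjoint,
#' exhaustive, and each class is spread across folds as evenly as
#' possible (per-fold class counts differ by at most one record).
#'
#' @param labels class labels, one per record.
#' @param k number of folds (default 5).
#' @param seed optional integer seed; identical seeds give identical
#'   folds.
#' @return integer vector of fold ids in `1:k`, one per record.
#' @export
make_cv_folds <- function(labels, k = 5, seed = NULL) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    small <- names(tab)[which.min(tab)]
    stop(sprintf("class '%s' has %d records, fewer than k = %d folds",
                 small, min(tab), k))
  }
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' Stratified train/test split
#'
#' @param labels class labels, one per record.
#' @param ratio fraction assigned to the training portion (default 0.8,
#'   the conventional 8:2 split).
#' @param seed optional integer seed.
#' @return logical vector, `TRUE` for training records. Every class
#'   contributes at least one record to each side.
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = NULL) {
  stopifnot(ratio > 0, ratio < 1)
  labels <- as.factor(labels)
  if (!is.null(seed)) set.seed(seed)
  train <- logical(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- min(max(round(ratio * length(idx)), 1L), length(idx) - 1L)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}
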