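# Stage 2 detection: naive threshold rule, bivariate-normal prediction
# ellipses, classifier backends on (X1, X2), and screening of
# unlabeled manufacturers.

#' Naive decision rule
#'
#' A month record is suspicious iff `X1 > t1` AND `X2 > t2`, strictly.
#' The default thresholds of 6 (natural-log scale) flag months where
#' smoothed sales exceed smoothed recorded purchases more than
#' `e^6 > 400` fold both in the same month and against the previous
#' month's purchases.
#'
#' @param t1,t2 finite thresholds on X1 and X2 (default 6).
#' @return a `decision_rule`.
#' @export
decision_rule <- function(t1 = 6, t2 = 6) {
  stopifnot(is.finite(t1), is.finite(t2))
  structure(list(t1 = t1, t2 = t2), class = "decision_rule")
}

#' Classify month records with the naive rule
#'
#' @param x1,x2 numeric feature vectors (clamped records allowed). A
#'   missing `x2` (the first emitted month of a series) classifies as
#'   benchmark by convention; those records are marked in the
#'   `"partial"` attribute.
#' @param rule a [decision_rule()].
#' @return factor with levels `benchmark`, `suspicious`; boundary ties
#'   (exactly at a threshold) are benchmark.
#' @export
naive_rule_classify <- function(x1, x2, rule = decision_rule()) {
  stopifnot(length(x1) == length(x2))
  partial <- is.na(x2)
  sus <- !is.na(x1) & !partial & x1 > rule$t1 & x2 > rule$t2
  out <- factor(ifelse(sus, "suspicious", "benchmark"),
                levels = c("benchmark", "suspicious"))
  attr(out, "partial") <- partial
  out
}

#' Fit a bivariate-normal prediction ellipse
#'
#' Center is the sample mean of the benchmark features, shape the
#' sample covariance; a point p lies inside the level-q region iff its
#' squared Mahalanobis distance is at most the chi-square quantile at q
#' with 2 degrees of freedom. The regions are descriptive aids and an
#' optional outlier screen; they do not feed the classifiers.
#'
#' @param x two-column numeric matrix or data frame of (X1, X2)
#'   benchmark records; non-finite rows are dropped, at least 3
#'   non-degenerate rows required.
#' @param level coverage probability in (0, 1), conventionally 0.95 or
#'   0.99.
#' @return an `ellipse_region` with `center`, `shape`, `level` and
#'   `radius2` (the chi-square quantile).
#' @export
fit_ellipse <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  x <- as.matrix(x[, 1:2])
  x <- x[stats::complete.cases(x) & is.finite(rowSums(x)), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 non-degenerate records")
  shape <- stats::cov(x)
  if (!all(is.finite(shape)) || rcond(shape) < 1e-12)
    stop("singular covariance: jitter the features or supply more data")
  structure(list(center = colMeans(x), shape = shape, level = level,
                 radius2 = stats::qchisq(level, df = 2), n = nrow(x)),
            class = "ellipse_region")
}

#' @export
print.ellipse_region <- function(x, ...) {
  cat(sprintf("Bivariate prediction ellipse (level %.0f%%, n = %d)\n",
              100 * x$level, x$n))
  cat(sprintf("  center: (%.3f, %.3f); boundary radius^2 = %.4f\n",
              x$center[1], x$center[2], x$radius2))
  invisible(x)
}

#' Ellipse membership test
#'
#' @param region an `ellipse_region`.
#' @param x two-column matrix or data frame of points.
#' @return logical vector, `TRUE` for points inside or on the boundary.
#' @export
in_ellipse <- function(region, x) {
  x <- as.matrix(x[, 1:2])
  stats::mahalanobis(x, region$center, region$shape) <= region$radius2
}

#' Sample from a fitted ellipse's bivariate normal
#'
#' @param region an `ellipse_region`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return n x 2 matrix of draws from `N(center, shape)`.
#' @export
sample_ellipse <- function(region, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  MASS::mvrnorm(n, region$center, region$shape)
}

#' Boundary coordinates of an ellipse (for plotting)
#'
#' @param region an `ellipse_region`.
#' @param n number of boundary points.
#' @return n x 2 matrix tracing the boundary.
#' @export
ellipse_boundary <- function(region, n = 361) {
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(theta), sin(theta)) * sqrt(region$radius2)
  e <- eigen(region$shape, symmetric = TRUE)
  t(region$center + e$vectors %*% (t(circ) * sqrt(pmax(e$values, 0))))
}

#' Train a classifier on the turnover features
#'
#' Fits the chosen backend on (X1, X2) with an 80/20 stratified split
#' and k-fold cross-validated hyperparameters, reporting sensitivity
#' (probability of identifying a problematic B month record),
#' specificity (identifying a benchmark A record) and error rate on the
#' held-out portion, plus pooled out-of-fold CV rates. Records with
#' clamped features are excluded by default (they are distributional
#' outliers by construction; the naive rule still accepts them), as are
#' invalid records and those lacking `X2`.
#'
#' @param features feature data frame from [compute_features()] /
#'   [turnover_features()].
#' @param labels class labels aligned with `features` rows: `"A"`
#'   (benchmark) or `"B"` (problematic).
#' @param method backend name, as in [train_sieve()].
#' @param seed integer seed for split, folds and fitting.
#' @param include_clamped keep clamped records (default `FALSE`).
#' @param cv_folds cross-validation folds (default 5, reduced if a
#'   class is smaller).
#' @return list with `classifier` (an `alarm_classifier`) and `report`
#'   (an `eval_report`).
#' @export
train_alarm_classifier <- function(features, labels,
                                   method = c("random-forest", "knn",
                                              "linear-svm", "logistic",
                                              "feedforward-net"),
                                   seed = 1L, include_clamped = FALSE,
                                   cv_folds = 5) {
  method <- match.arg(method)
  labels <- as.character(labels)
  keep <- features$valid & !is.na(features$X2) &
    (include_clamped | !features$clamped)
  X <- as.matrix(features[keep, c("X1", "X2")])
  y <- factor(labels[keep], levels = c("A", "B"))
  if (any(table(y) == 0))
    stop("both A and B month records must be present")
  fit <- .train_with_cv(X, y, method, seed = as.integer(seed),
                        cv_folds = min(cv_folds, min(table(y))))
  classifier <- structure(list(method = method, backend = fit$model,
                               params = fit$report$params,
                               seed = as.integer(seed)),
                          class = "alarm_classifier")
  list(classifier = classifier, report = fit$report)
}

#' @export
predict.alarm_classifier <- function(object, features, ...) {
  X <- as.matrix(features[, c("X1", "X2")])
  ok <- stats::complete.cases(X)
  out <- factor(rep("A", nrow(X)), levels = c("A", "B"))
  if (any(ok))
    out[ok] <- .predict_backend(object$backend, X[ok, , drop = FALSE])
  out
}

#' Screen unlabeled manufacturers
#'
#' Labels every month record of the supplied (typically C-class)
#' features with the naive rule or a trained classifier, then
#' aggregates to manufacturers: a manufacturer is flagged iff at least
#' `k` of its month records are suspicious. A flag means "suspicious
#' enough to inspect further", not a finding of wrongdoing.
#'
#' @param features feature data frame (see [turnover_features()]).
#' @param model a [decision_rule()] or an `alarm_classifier`.
#' @param k minimum number of suspicious months to flag a manufacturer
#'   (default 1).
#' @return an `alarm_report`: `records` (per-month labels),
#'   `manufacturers` (per-manufacturer counts and flags),
#'   `flagged_ids`, `month_flag_fraction`, and the `method` provenance.
#' @export
screen_unlabeled <- function(features, model, k = 1) {
  if (is.null(features) || nrow(features) == 0) {
    return(structure(list(records = data.frame(),
                          manufacturers = data.frame(),
                          flagged_ids = character(0),
                          month_flag_fraction = NA_real_,
                          method = class(model)[1], k = k),
                     class = "alarm_report"))
  }
  if (inherits(model, "decision_rule")) {
    lab <- naive_rule_classify(features$X1, features$X2, model)
    lab[!features$valid] <- "benchmark"
    method <- sprintf("naive rule (t1 = %g, t2 = %g)", model$t1, model$t2)
  } else if (inherits(model, "alarm_classifier")) {
    cls <- predict(model, features)
    lab <- factor(ifelse(features$valid & cls == "B",
                         "suspicious", "benchmark"),
                  levels = c("benchmark", "suspicious"))
    method <- model$method
  } else stop("model must be a decision_rule or alarm_classifier")

  records <- data.frame(manufacturer_id = features$manufacturer_id,
                        month = features$month, label = lab,
                        stringsAsFactors = FALSE)
  n_sus <- tapply(records$label == "suspicious",
                  records$manufacturer_id, sum)
  n_all <- tapply(rep(1L, nrow(records)), records$manufacturer_id, sum)
  manufacturers <- data.frame(manufacturer_id = names(n_sus),
                              n_months = as.integer(n_all),
                              n_suspicious = as.integer(n_sus),
                              flagged = as.integer(n_sus) >= k,
                              row.names = NULL, stringsAsFactors = FALSE)
  structure(list(records = records, manufacturers = manufacturers,
                 flagged_ids = manufacturers$manufacturer_id[manufacturers$flagged],
                 month_flag_fraction = mean(records$label == "suspicious"),
                 method = method, k = k),
            class = "alarm_report")
}

#' @export
print.alarm_report <- function(x, ...) {
  cat("Alarm screening report —", x$method, "\n")
  cat(sprintf("  %d month records, %s flagged suspicious\n",
              nrow(x$records), .pct(x$month_flag_fraction)))
  cat(sprintf("  %d of %d manufacturers flagged (>= %d suspicious month%s)\n",
              length(x$flagged_ids), nrow(x$manufacturers), x$k,
              if (x$k == 1) "" else "s"))
  if (length(x$flagged_ids))
    cat("  flagged:", paste(x$flagged_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth labels for smoothed month records
#'
#' A feature record at month i summarizes raw months i-2..i (and its
#' lag feature reaches back to i-3). It is labelled problematic (`"B"`)
#' iff all raw months in that span are flagged suspicious in the
#' generator's ground truth; records whose windows mix regimes carry
#' intermediate features and are labelled benchmark.
#'
#' @param features feature data frame from [turnover_features()].
#' @param ground_truth ground-truth data frame from
#'   [generate_invoices()].
#' @param window number of trailing raw months a record summarizes
#'   (default 4 = the union of the D_i and D_{i-1} windows).
#' @return factor of `"A"`/`"B"` labels aligned with `features` rows.
#' @export
suspicious_record_labels <- function(features, ground_truth, window = 4) {
  gt <- ground_truth[order(ground_truth$manufacturer_id,
                           ground_truth$month_index), ]
  flags <- split(gt$suspicious, gt$manufacturer_id)
  lab <- vapply(seq_len(nrow(features)), function(r) {
    f <- flags[[features$manufacturer_id[r]]]
    i <- features$month_index[r]
    lo <- i - window + 1
    if (is.null(f) || lo < 1) FALSE else all(f[lo:i])
  }, logical(1))
  factor(ifelse(lab, "B", "A"), levels = c("A", "B"))
}

#' Scatter plot of turnover features with prediction ellipses
#'
#' The benchmark-vs-problematic scatter on (X1, X2) with 95%/99%
#' prediction ellipses fitted to the benchmark records and the naive
#' rule thresholds drawn as dashed lines.
#'
#' @param features feature data frame.
#' @param labels class labels aligned with rows (`"A"`, `"B"`,
#'   optionally `"C"`).
#' @param levels ellipse coverage levels.
#' @param rule optional [decision_rule()] whose thresholds to draw.
#' @param file optional path; if given, a PNG is written there.
#' @return the fitted ellipses, invisibly.
#' @export
plot_alarm_features <- function(features, labels,
                                levels = c(0.95, 0.99),
                                rule = decision_rule(), file = NULL) {
  ok <- features$valid & !is.na(features$X2)
  x <- features[ok, c("X1", "X2")]
  labels <- as.character(labels)[ok]
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 640)
    on.exit(grDevices::dev.off())
  }
  cols <- c(A = "#2166ac", B = "#b2182b", C = "#999999")
  pchs <- c(A = 1, B = 17, C = 3)
  graphics::plot(x$X1, x$X2, col = cols[labels], pch = pchs[labels],
                 xlab = expression(X[1] == log(U[i] / D[i])),
                 ylab = expression(X[2] == log(U[i] / D[i - 1])),
                 main = "Monthly log turnover ratios")
  ells <- lapply(levels, function(lv) {
    e <- fit_ellipse(x[labels == "A", ], level = lv)
    b <- ellipse_boundary(e)
    graphics::lines(b[, 1], b[, 2], lty = 1, col = "#555555")
    e
  })
  if (!is.null(rule))
    graphics::abline(v = rule$t1, h = rule$t2, lty = 2, col = "#b2182b")
  graphics::legend("topleft", legend = unique(labels),
                   col = cols[unique(labels)], pch = pchs[unique(labels)],
                   bty = "n")
  invisible(ells)
}
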