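# Shared classifier backend engine used by both pipeline stages.
# Each backend maps a numeric feature matrix to a binary label via an
# established implementation; hyperparameters come from small fixed
# grids chosen by stratified k-fold cross-validation.

.methods <- c("knn", "linear-svm", "logistic", "feedforward-net",
              "random-forest")

.default_grid <- function(method) {
  switch(method,
         "knn" = expand.grid(k = c(3, 5, 7)),
         "linear-svm" = expand.grid(cost = c(0.1, 1, 10)),
         "logistic" = data.frame(intercept = TRUE),
         "feedforward-net" = expand.grid(size = c(3, 5), decay = 0.1),
         "random-forest" = data.frame(ntree = 200),
         stop("unknown method '", method, "'; use one of: ",
              paste(.methods, collapse = ", ")))
}

.fit_backend <- function(X, y, method, params, seed) {
  set.seed(seed)
  fit <- switch(method,
    "knn" = list(X = X, y = y, k = params$k),
    "linear-svm" = e1071::svm(x = X, y = y, kernel = "linear",
                              cost = params$cost, scale = FALSE),
    "logistic" = {
      d <- as.data.frame(X)
      names(d) <- paste0("f", seq_len(ncol(X)))
      d$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
    },
    "feedforward-net" = nnet::nnet(x = X,
                                   y = as.numeric(y == levels(y)[2]),
                                   size = params$size, decay = params$decay,
                                   maxit = 300, trace = FALSE),
    "random-forest" = randomForest::randomForest(x = X, y = y,
                                                 ntree = params$ntree))
  list(method = method, fit = fit, params = params, levels = levels(y))
}

.predict_backend <- function(model, X) {
  lv <- model$levels
  pred <- switch(model$method,
    "knn" = as.character(class::knn(model$fit$X, X, model$fit$y,
                                    k = model$fit$k)),
    "linear-svm" = as.character(stats::predict(model$fit, X)),
    "logistic" = {
      d <- as.data.frame(X)
      names(d) <- paste0("f", seq_len(ncol(X)))
      p <- suppressWarnings(stats::predict(model$fit, newdata = d,
                                           type = "response"))
      ifelse(p > 0.5, lv[2], lv[1])
    },
    "feedforward-net" = {
      p <- as.numeric(stats::predict(model$fit, X))
      ifelse(p > 0.5, lv[2], lv[1])
    },
    "random-forest" = as.character(stats::predict(model$fit, X)))
  factor(pred, levels = lv)
}

# 80/20 stratified split, grid search by k-fold CV inside the training
# portion, final fit on the whole training portion, metrics on the
# held-out 20% plus pooled out-of-fold CV metrics. Returns the fitted
# backend and an eval_report (with cv_* fields attached).
.train_with_cv <- function(X, y, method, seed, cv_folds = 5,
                           split_ratio = 0.8, grid = NULL) {
  stopifnot(is.matrix(X), nlevels(y) == 2)
  if (any(table(y) == 0)) stop("both classes must be present")
  if (length(y) < 10) stop("need at least 10 records for an 8:2 split")
  if (is.null(grid)) grid <- .default_grid(method)

  train <- stratified_split(y, ratio = split_ratio, seed = seed)
  X_tr <- X[train, , drop = FALSE]; y_tr <- y[train]
  X_te <- X[!train, , drop = FALSE]; y_te <- y[!train]

  k_eff <- min(cv_folds, min(table(y_tr)))
  folds <- make_cv_folds(y_tr, k = k_eff, seed = seed + 1L)

  cv_err <- numeric(nrow(grid))
  oof <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pred <- factor(rep(NA_character_, length(y_tr)), levels = levels(y))
    for (f in seq_len(k_eff)) {
      m <- .fit_backend(X_tr[folds != f, , drop = FALSE], y_tr[folds != f],
                        method, grid[g, , drop = FALSE], seed = seed + 2L)
      pred[folds == f] <- .predict_backend(m, X_tr[folds == f, , drop = FALSE])
    }
    cv_err[g] <- mean(pred != y_tr)
    oof[[g]] <- pred
  }
  best <- which.min(cv_err)  # ties: first grid row

  model <- .fit_backend(X_tr, y_tr, method, grid[best, , drop = FALSE],
                        seed = seed + 3L)
  pred_te <- .predict_backend(model, X_te)

  pos <- levels(y)[2]
  report <- evaluate_predictions(y_te, pred_te, positive = pos,
                                 method = method, seed = seed)
  cv_rep <- evaluate_predictions(y_tr, oof[[best]], positive = pos,
                                 method = paste0(method, " (cv)"),
                                 seed = seed)
  report$n_train <- length(y_tr)
  report$n_test <- length(y_te)
  report$cv_sensitivity <- cv_rep$sensitivity
  report$cv_specificity <- cv_rep$specificity
  report$cv_error_rate <- cv_rep$error_rate
  report$params <- as.list(grid[best, , drop = FALSE])
  list(model = model, report = report)
}
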