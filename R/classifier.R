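#' Z-score scaler fitted on training data
#'
#' Per-feature centering and scaling estimated on the training table only:
#' center = mean, scale = population standard deviation. Zero-variance
#' (constant) features get scale 1 and are flagged, so they pass through
#' centered but unscaled.
#'
#' @param train Feature table (training rows only).
#' @param features Feature columns to scale; default all.
#' @return List of class `"eus_scaler"`: `center`, `scale` (named
#'   numerics), `constant` (names of flagged features).
#' @export
fit_scaler <- function(train, features = feature_columns(train)) {
  if (nrow(train) == 0) abort("empty training table")
  center <- vapply(features, function(f) mean(train[[f]]), numeric(1))
  scale <- vapply(features, function(f) {
    v <- train[[f]]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  constant <- names(scale)[scale == 0]
  scale[scale == 0] <- 1
  structure(list(center = center, scale = scale, constant = constant),
            class = "eus_scaler")
}

#' @param params An `"eus_scaler"` from [fit_scaler()].
#' @param table Feature table to transform (training or unseen rows).
#' @rdname fit_scaler
#' @return `apply_scaler()`: the table with scaled feature columns.
#' @export
apply_scaler <- function(params, table) {
  for (f in names(params$center)) {
    table[[f]] <- (table[[f]] - unname(params$center[f])) /
      unname(params$scale[f])
  }
  table
}

#' SVM settings
#'
#' Defaults: RBF kernel, cost C = 1, gamma = 1 / (number of features) —
#' chosen for reproducibility after z-scoring. `tune = TRUE` enables an
#' inner 5-fold grid search over C in 2^-5..2^15 and gamma in 2^-15..2^3
#' (steps of powers of 4), selected by correct classification rate with
#' deterministic stratified folds.
#'
#' @param kernel `"radial"` or `"linear"`.
#' @param cost Cost parameter C.
#' @param gamma RBF width; `NULL` means 1/n_features.
#' @param tune Run the inner grid search?
#' @param class_weights Optional named weights (`"0"`, `"1"`) for class
#'   imbalance; the default applies none.
#' @return List of class `"eus_svm_config"`.
#' @export
svm_config <- function(kernel = c("radial", "linear"), cost = 1,
                       gamma = NULL, tune = FALSE, class_weights = NULL) {
  structure(list(kernel = match.arg(kernel), cost = cost, gamma = gamma,
                 tune = tune, class_weights = class_weights),
            class = "eus_svm_config")
}

#' Train the SVM on a (scaled) feature table
#'
#' Fits a binary support vector classifier (libsvm, via e1071) on the
#' given feature subset. The table is used as-is: scale it first with
#' [fit_scaler()]/[apply_scaler()]. Training is deterministic given the
#' data order and configuration.
#'
#' @param train Feature table with both classes, features already scaled.
#' @param features Feature columns to use, in order.
#' @param config A [svm_config()].
#' @return Object of class `"eus_svm"` wrapping the fit; predict with
#'   [predict.eus_svm()].
#' @export
train_svm <- function(train, features = feature_columns(train),
                      config = svm_config()) {
  y <- factor(train$label, levels = c(0, 1))
  if (any(table(y) == 0)) abort("training set must contain both classes")
  x <- as.matrix(train[, features, drop = FALSE])
  gamma <- config$gamma %||% (1 / length(features))
  cost <- config$cost
  if (isTRUE(config$tune)) {
    g <- tune_svm_grid(x, y, config)
    cost <- g$cost
    gamma <- g$gamma
  }
  fit <- e1071::svm(x, y, scale = FALSE, kernel = config$kernel,
                    cost = cost, gamma = gamma,
                    class.weights = config$class_weights)
  structure(list(fit = fit, features = features, kernel = config$kernel,
                 cost = cost, gamma = gamma),
            class = "eus_svm")
}

# Deterministic stratified 5-fold grid search scored by CCR.
tune_svm_grid <- function(x, y, config) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- rep_len(1:5, length(idx))
  }
  grid <- expand.grid(cost = 2^seq(-5, 15, by = 2),
                      gamma = 2^seq(-15, 3, by = 2))
  ccr <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (f in 1:5) {
      tr <- folds != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], scale = FALSE,
                        kernel = config$kernel, cost = grid$cost[i],
                        gamma = grid$gamma[i],
                        class.weights = config$class_weights)
      correct <- correct + sum(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(ccr)  # first max: smallest cost, then gamma
  list(cost = grid$cost[best], gamma = grid$gamma[best])
}

#' Predict lesion class with a trained SVM
#'
#' Returns one label per row, PC = 1 / CP = 0. Prediction goes through the
#' decision values so the tie at decision value exactly 0 is resolved
#' deterministically to class 0 (CP).
#'
#' @param object An `"eus_svm"` from [train_svm()].
#' @param newdata Feature table whose feature columns include exactly the
#'   model's features (same scaling as training).
#' @param ... Unused.
#' @return Integer vector of 0/1 labels.
#' @export
predict.eus_svm <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0)
    abort(paste0("newdata lacks model features: ",
                 paste(missing, collapse = ", ")))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  pr <- predict(object$fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  classes <- strsplit(colnames(dv)[1], "/")[[1]]  # "A/B": dv > 0 -> A
  lab <- ifelse(dv[, 1] > 0, classes[1],
                ifelse(dv[, 1] < 0, classes[2], "0"))
  as.integer(lab)
}

#' @export
print.eus_svm <- function(x, ...) {
  cat(sprintf("SVM classifier (%s kernel, C = %g, gamma = %g, %d features)\n",
              x$kernel, x$cost, x$gamma, length(x$features)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
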