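#' Stratified half-and-half split
#'
#' Uniform random split of the cohort into training and testing halves,
#' stratified per class: `floor(n_class / 2)` cases of each class go to the
#' training side, the rest to testing. With the reference cohort sizes of
#' 262 PC and 126 CP this yields 194 training cases (131 PC + 63 CP) and
#' 194 testing cases for every seed. Reproducible given the seed.
#'
#' @param labels Integer 0/1 label vector (PC = 1).
#' @param seed Integer seed.
#' @return List of class `"eus_split"`: `train`, `test` (disjoint index
#'   vectors into `labels` whose union is all cases), `seed`.
#' @export
stratified_half_split <- function(labels, seed) {
  if (min(table(factor(labels, levels = c(0, 1)))) < 2)
    abort("each class needs at least 2 cases")
  train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(c(0, 1), function(cl) {
      idx <- which(labels == cl)
      sample(idx, floor(length(idx) / 2))
    }))
  })
  train <- sort(train)
  structure(list(train = train,
                 test = setdiff(seq_along(labels), train),
                 seed = as.integer(seed)),
            class = "eus_split")
}

#' Confusion matrix and diagnostic metrics
#'
#' `confusion_counts()` tallies TP/FP/TN/FN with pancreatic cancer (label
#' 1) as the positive class. `confusion_metrics()` converts counts to the
#' five diagnostic metrics in percent: accuracy (TP+TN)/N, sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN). A
#' zero denominator yields `NA` (flagged undefined; such trials are
#' excluded from protocol averages for that metric).
#'
#' @param truth,pred Integer 0/1 vectors.
#' @return `confusion_counts()`: list of class `"eus_confusion"` with
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(tp = sum(truth == 1 & pred == 1),
                 fp = sum(truth == 0 & pred == 1),
                 tn = sum(truth == 0 & pred == 0),
                 fn = sum(truth == 1 & pred == 0)),
            class = "eus_confusion")
}

#' @param cm An `"eus_confusion"` (or list with `tp`, `fp`, `tn`, `fn`).
#' @rdname confusion_counts
#' @return `confusion_metrics()`: named numeric vector (percent) of
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(cm) {
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) abort("empty confusion matrix")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(accuracy = 100 * (cm$tp + cm$tn) / n,
    sensitivity = rate(cm$tp, cm$tp + cm$fn),
    specificity = rate(cm$tn, cm$tn + cm$fp),
    ppv = rate(cm$tp, cm$tp + cm$fp),
    npv = rate(cm$tn, cm$tn + cm$fn))
}

run_one_trial <- function(table, features, split, svm) {
  train <- table[split$train, , drop = FALSE]
  test <- table[split$test, , drop = FALSE]
  scaler <- fit_scaler(train, features)
  model <- train_svm(apply_scaler(scaler, train), features, svm)
  pred <- predict(model, apply_scaler(scaler, test))
  confusion_counts(test$label, pred)
}

#' Repeated stratified half-and-half validation
#'
#' The primary validation protocol: `n_trials` times (default 200, to damp
#' the variance from the limited cohort size), draw a fresh stratified
#' half split (seed + trial - 1), fit the z-score scaler on the training
#' half only, train the SVM, predict the testing half, and compute the
#' five diagnostic metrics. Metrics are averaged per trial; the standard
#' error is the across-trial sample SD divided by sqrt(n_trials), with
#' undefined (zero-denominator) trials excluded per metric.
#'
#' @param table Feature table.
#' @param features Feature subset to classify with.
#' @param n_trials Number of random split trials.
#' @param seed Integer seed; trial t uses seed + t - 1.
#' @param svm A [svm_config()].
#' @return Object of class `"eus_metrics"`; see [tidy.eus_metrics()] /
#'   [glance.eus_metrics()].
#' @export
half_and_half_eval <- function(table, features, n_trials = 200L, seed = 1L,
                               svm = svm_config()) {
  trials <- purrr::map(seq_len(n_trials), function(t) {
    split <- stratified_half_split(table$label, seed + t - 1L)
    m <- confusion_metrics(run_one_trial(table, features, split, svm))
    dplyr::bind_cols(tibble(trial = t), as_tibble(as.list(m)))
  })
  per_trial <- dplyr::bind_rows(trials)
  new_metrics_report(per_trial, protocol = "half-and-half",
                     n_trials = n_trials, seed = as.integer(seed),
                     features = features)
}

#' Leave-one-out cross-validation
#'
#' Each case is tested exactly once against a model trained (with its own
#' scaler) on all remaining cases; the N per-case predictions are pooled
#' into a single confusion matrix and one metric set (no standard error —
#' the protocol is deterministic).
#'
#' @inheritParams half_and_half_eval
#' @return Object of class `"eus_metrics"` with a single pooled row.
#' @export
loocv_eval <- function(table, features, svm = svm_config()) {
  if (min(table(factor(table$label, levels = c(0, 1)))) < 2)
    abort("each class needs at least 2 cases")
  n <- nrow(table)
  pred <- integer(n)
  for (i in seq_len(n)) {
    split <- list(train = setdiff(seq_len(n), i), test = i)
    train <- table[split$train, , drop = FALSE]
    scaler <- fit_scaler(train, features)
    model <- train_svm(apply_scaler(scaler, train), features, svm)
    pred[i] <- predict(model, apply_scaler(scaler, table[i, , drop = FALSE]))
  }
  m <- confusion_metrics(confusion_counts(table$label, pred))
  per_trial <- dplyr::bind_cols(tibble(trial = 1L), as_tibble(as.list(m)))
  new_metrics_report(per_trial, protocol = "leave-one-out", n_trials = 1L,
                     seed = NA_integer_, features = features)
}

new_metrics_report <- function(per_trial, protocol, n_trials, seed, features) {
  structure(list(per_trial = per_trial, protocol = protocol,
                 n_trials = n_trials, seed = seed, features = features),
            class = "eus_metrics")
}

metric_names <- function() c("accuracy", "sensitivity", "specificity", "ppv", "npv")

#' Tidy a validation report
#'
#' `tidy()` returns one row per diagnostic metric with its across-trial
#' mean, standard error (sample SD / sqrt(trials used); 0 for a single
#' pooled trial) and the number of trials in which the metric was defined.
#' `glance()` returns a one-row summary of the means.
#'
#' @param x An `"eus_metrics"` report.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy eus_metrics
#' @export
tidy.eus_metrics <- function(x, ...) {
  purrr::map_dfr(metric_names(), function(m) {
    v <- x$per_trial[[m]]
    v <- v[!is.na(v)]
    n <- length(v)
    tibble(metric = m,
           mean = mean(v),
           se = if (n > 1) sd(v) / sqrt(n) else 0,
           n_defined = n)
  })
}

#' @rdname tidy.eus_metrics
#' @method glance eus_metrics
#' @export
glance.eus_metrics <- function(x, ...) {
  s <- tidy(x)
  out <- as_tibble(as.list(stats::setNames(s$mean, s$metric)))
  out$n_trials <- x$n_trials
  out$protocol <- x$protocol
  out
}

#' @export
print.eus_metrics <- function(x, ...) {
  s <- tidy(x)
  cat(sprintf("Validation: %s (%d trial%s, %d features)\n", x$protocol,
              x$n_trials, if (x$n_trials == 1) "" else "s",
              length(x$features)))
  for (i in seq_len(nrow(s))) {
    if (x$n_trials > 1) {
      cat(sprintf("  %-12s %6.2f +/- %.4f %%  (defined in %d trials)\n",
                  s$metric[i], s$mean[i], s$se[i], s$n_defined[i]))
    } else {
      cat(sprintf("  %-12s %6.2f %%\n", s$metric[i], s$mean[i]))
    }
  }
  invisible(x)
}

#' Side-by-side report of the two validation protocols
#'
#' Formats the half-and-half and leave-one-out reports as the standard
#' mean (+/- SE) table, one row per metric, one column per protocol.
#'
#' @param half,loo `"eus_metrics"` reports.
#' @return A tibble (metric, half_and_half, leave_one_out).
#' @export
report_table <- function(half, loo) {
  th <- tidy(half); tl <- tidy(loo)
  tibble(
    metric = th$metric,
    half_and_half = sprintf("%.2f +/- %.2f%%", th$mean, th$se),
    leave_one_out = sprintf("%.2f%%", tl$mean)
  )
}
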