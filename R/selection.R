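#' Robust between-class distance of a single feature
#'
#' The separation score used by the first selection stage: the absolute gap
#' between the class medians, normalized by the sum of the class median
#' absolute deviations (MAD, unscaled, about the class median):
#' \deqn{d = |med(x_{PC}) - med(x_{CP})| / (MAD_{PC} + MAD_{CP} + \epsilon)}
#' with \eqn{\epsilon = 10^{-12}}. A larger distance means the feature
#' separates the classes better. The score is symmetric in the two classes,
#' translation- and scale-invariant, and 0 exactly when the medians
#' coincide.
#'
#' @param values_pc,values_cp Feature values in each class (>= 2 each).
#' @return Nonnegative scalar.
#' @export
class_distance <- function(values_pc, values_cp) {
  if (length(values_pc) < 2 || length(values_cp) < 2)
    abort("each class needs at least 2 values")
  gap <- abs(median(values_pc) - median(values_cp))
  spread <- stats::mad(values_pc, constant = 1) +
    stats::mad(values_cp, constant = 1)
  gap / (spread + 1e-12)
}

#' Rank features by between-class distance
#'
#' Stage 1 of feature selection: scores every feature column of a labelled
#' feature table with [class_distance()] and ranks them in descending
#' order; ties are broken by canonical (column) order. The top `m` features
#' (default 25) form the preliminary pool handed to [sfs_curve()].
#'
#' @param table Feature table (`case_id`, `label`, feature columns) with
#'   both classes present.
#' @param m Size of the preliminary pool (default 25).
#' @return A tibble of class `"eus_ranking"` with columns `rank`,
#'   `feature`, `score`, `selected` (logical, `TRUE` for the top `m`),
#'   covering all features; attribute `m`.
#' @export
rank_features <- function(table, m = 25L) {
  feats <- feature_columns(table)
  if (m > length(feats)) abort("m exceeds the number of features")
  lab <- table$label
  if (length(unique(lab)) < 2) abort("feature table must contain both classes")
  scores <- vapply(feats, function(f)
    class_distance(table[[f]][lab == 1], table[[f]][lab == 0]), numeric(1))
  ord <- order(-scores, seq_along(scores))  # stable: canonical order on ties
  out <- tibble(
    rank = seq_along(feats),
    feature = feats[ord],
    score = unname(scores[ord]),
    selected = seq_along(feats) <= m
  )
  structure(out, class = c("eus_ranking", class(out)), m = as.integer(m))
}

#' Sequential forward selection curve
#'
#' Stage 2 of feature selection. In the default `"ranked"` mode the
#' class-distance-ranked features are added one by one (the feature set at
#' step k is the first k ranked features) and the correct classification
#' rate (CCR, percent) of each prefix is measured with the repeated
#' stratified half-and-half protocol of [half_and_half_eval()]. The
#' optional `"greedy"` mode is classic SFS: each step adds the candidate
#' that maximizes CCR (ties to the better-ranked candidate). The optimum is
#' the maximum-CCR step, smallest k on ties.
#'
#' Selection reuses the full table, mirroring the original protocol in
#' which all cases inform selection before validation; use an independent
#' seed for the final validation (see the package vignette on the optimism
#' this induces).
#'
#' @param table Feature table.
#' @param ranking An `"eus_ranking"` from [rank_features()] (its top-`m`
#'   pool is the candidate set).
#' @param mode `"ranked"` (default) or `"greedy"`.
#' @param n_trials Half-and-half trials per CCR evaluation (default 200).
#' @param seed Integer seed for the evaluation protocol.
#' @param svm SVM settings, a [svm_config()].
#' @return A tibble of class `"eus_sfs_trace"` with columns `k`,
#'   `feature_added`, `ccr`; attributes `optimum` (list `k`, `ccr`),
#'   `mode`, `seed`.
#' @export
sfs_curve <- function(table, ranking, mode = c("ranked", "greedy"),
                      n_trials = 200L, seed = 1L, svm = svm_config()) {
  mode <- match.arg(mode)
  pool <- ranking$feature[ranking$selected]
  if (length(pool) == 0) abort("ranking has no selected features")
  eval_ccr <- function(features) {
    rep <- half_and_half_eval(table, features, n_trials = n_trials,
                              seed = seed, svm = svm)
    glance(rep)$accuracy
  }
  if (mode == "ranked") {
    added <- pool
    ccr <- numeric(length(pool))
    for (k in seq_along(pool)) ccr[k] <- eval_ccr(pool[seq_len(k)])
  } else {
    remaining <- pool
    added <- character(0)
    ccr <- numeric(0)
    while (length(remaining) > 0) {
      cand_ccr <- vapply(remaining, function(f) eval_ccr(c(added, f)),
                         numeric(1))
      best <- which.max(cand_ccr)  # first max: better-ranked candidate wins
      added <- c(added, remaining[best])
      ccr <- c(ccr, cand_ccr[best])
      remaining <- remaining[-best]
    }
  }
  opt <- curve_optimum(ccr)
  out <- tibble(k = seq_along(added), feature_added = added, ccr = ccr)
  structure(out, class = c("eus_sfs_trace", class(out)),
            optimum = opt, mode = mode, seed = as.integer(seed))
}

#' Optimum of a CCR-versus-subset-size curve
#'
#' Returns the subset size with the highest correct classification rate
#' (smallest size on ties) and that rate.
#'
#' @param ccr_by_k Numeric vector of CCR percentages, element k being the
#'   CCR of the first k features.
#' @return List with `k` (1-based) and `ccr`.
#' @export
curve_optimum <- function(ccr_by_k) {
  if (length(ccr_by_k) == 0) abort("empty CCR curve")
  if (any(ccr_by_k < 0 | ccr_by_k > 100)) abort("CCR values must be in [0, 100]")
  k <- which.max(ccr_by_k)  # which.max takes the first maximum
  list(k = as.integer(k), ccr = ccr_by_k[k])
}

#' @export
print.eus_ranking <- function(x, ...) {
  m <- attr(x, "m")
  cat(sprintf("Between-class distance ranking (%d features, top %d selected)\n",
              nrow(x), m))
  print(as_tibble(x), n = m)
  invisible(x)
}

#' @export
print.eus_sfs_trace <- function(x, ...) {
  opt <- attr(x, "optimum")
  cat(sprintf("Sequential forward selection (%s mode)\n", attr(x, "mode")))
  cat(sprintf("  k  = 1..%d, optimum k* = %d with CCR %.2f%% (error %.2f%%)\n",
              nrow(x), opt$k, opt$ccr, 100 - opt$ccr))
  print(as_tibble(x), n = nrow(x))
  invisible(x)
}
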