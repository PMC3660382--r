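#' Pipeline configuration
#'
#' Bundles every stage's settings with their module defaults: 64 grey
#' levels, GLCM distances 1 and 2, db4 wavelet at 3 levels, a preliminary
#' pool of m = 25 features, ranked-incremental SFS, default SVM settings,
#' and 200 validation trials. The configuration round-trips through JSON
#' unchanged ([write_config()] / [read_config()]).
#'
#' @param seed Master seed for every random stage.
#' @param levels,distances,wavelet_levels See [feature_config()].
#' @param m Preliminary pool size for [rank_features()].
#' @param sfs_mode `"ranked"` or `"greedy"`.
#' @param selection_trials Half-and-half trials per SFS CCR evaluation.
#' @param n_trials Validation trials for [half_and_half_eval()].
#' @param svm A [svm_config()].
#' @param simulate Synthetic-cohort settings (list: `n_pc`, `n_cp`,
#'   `size`), used when no feature CSV is given.
#' @param feature_csv Optional path to a precomputed feature table; when
#'   set, extraction is skipped.
#' @return List of class `"eus_config"`.
#' @export
eus_config <- function(seed = 1L, levels = 64L, distances = c(1L, 2L),
                       wavelet_levels = 3L, m = 25L,
                       sfs_mode = "ranked", selection_trials = 200L,
                       n_trials = 200L, svm = svm_config(),
                       simulate = list(n_pc = 60L, n_cp = 60L, size = c(64L, 64L)),
                       feature_csv = NULL) {
  structure(list(seed = as.integer(seed), levels = as.integer(levels),
                 distances = as.integer(distances),
                 wavelet_levels = as.integer(wavelet_levels),
                 m = as.integer(m), sfs_mode = sfs_mode,
                 selection_trials = as.integer(selection_trials),
                 n_trials = as.integer(n_trials), svm = unclass(svm),
                 simulate = simulate, feature_csv = feature_csv),
            class = "eus_config")
}

#' @param config An `"eus_config"`.
#' @param path JSON file path.
#' @rdname eus_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname eus_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- eus_config(
    seed = x$seed, levels = x$levels, distances = x$distances,
    wavelet_levels = x$wavelet_levels, m = x$m, sfs_mode = x$sfs_mode,
    selection_trials = x$selection_trials, n_trials = x$n_trials,
    svm = do.call(svm_config, x$svm[c("kernel", "cost", "gamma", "tune")]),
    simulate = x$simulate, feature_csv = x$feature_csv
  )
  cfg
}

config_hash <- function(config) {
  # small FNV-style hash of the serialized config; names every artifact
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (xor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Run the full diagnostic pipeline
#'
#' Executes extract -> rank -> SFS -> validate and persists every
#' intermediate in `out_dir`: the feature table (CSV + category sidecar),
#' the class-distance ranking, the SFS trace, both validation reports on
#' the optimum subset (JSON + a side-by-side text table), the
#' configuration, and a log naming the config hash and master seed.
#' Inputs are either a precomputed feature CSV (`config$feature_csv`) or a
#' synthetic cohort generated from `config$simulate`; both routes yield
#' identical downstream results for the same table. Reruns with the same
#' configuration reproduce the reports byte for byte.
#'
#' @param config An [eus_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the run artifacts (`features`,
#'   `ranking`, `trace`, `optimum`, `half`, `loo`, `dir`).
#' @export
run_pipeline <- function(config = eus_config(), out_dir = tempfile("eus_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "log.txt")
  say <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat(sprintf("run %s (seed %d)\n", hash, config$seed), file = logf)
  say("eustex %s, R %s", as.character(utils::packageVersion("eustex")),
      paste(R.version$major, R.version$minor, sep = "."))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  fcfg <- feature_config(config$levels, config$distances, config$wavelet_levels)
  tbl <- stage("extract", {
    if (!is.null(config$feature_csv)) {
      say("input: feature table %s", config$feature_csv)
      read_feature_table(config$feature_csv)
    } else {
      say("input: synthetic cohort (%d PC + %d CP, %dx%d, seed %d)",
          config$simulate$n_pc, config$simulate$n_cp,
          config$simulate$size[1], config$simulate$size[2], config$seed)
      cohort <- generate_cohort(n_pc = config$simulate$n_pc,
                                n_cp = config$simulate$n_cp,
                                size = config$simulate$size,
                                seed = config$seed)
      feature_table(cohort, fcfg)
    }
  })
  write_feature_table(tbl, file.path(out_dir, paste0("features_", hash, ".csv")))

  ranking <- stage("rank", rank_features(tbl, m = config$m))
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         ranking = as.data.frame(ranking)),
    file.path(out_dir, paste0("ranking_", hash, ".json")),
    auto_unbox = TRUE, digits = NA)

  svm <- do.call(svm_config, config$svm[c("kernel", "cost", "gamma", "tune")])
  trace <- stage("sfs", sfs_curve(tbl, ranking, mode = config$sfs_mode,
                                  n_trials = config$selection_trials,
                                  seed = config$seed + 1000L, svm = svm))
  opt <- attr(trace, "optimum")
  say("sfs optimum: k* = %d, CCR %.2f%%", opt$k, opt$ccr)
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed, mode = config$sfs_mode,
         optimum = opt, trace = as.data.frame(trace)),
    file.path(out_dir, paste0("sfs_trace_", hash, ".json")),
    auto_unbox = TRUE, digits = NA)

  best <- trace$feature_added[seq_len(opt$k)]
  half <- stage("evaluate", half_and_half_eval(tbl, best,
                                               n_trials = config$n_trials,
                                               seed = config$seed + 2000L,
                                               svm = svm))
  loo <- stage("evaluate", loocv_eval(tbl, best, svm = svm))
  for (nm in c("half", "loo")) {
    rep <- if (nm == "half") half else loo
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed, protocol = rep$protocol,
           features = rep$features, summary = as.data.frame(tidy(rep)),
           per_trial = as.data.frame(rep$per_trial)),
      file.path(out_dir, paste0("report_", nm, "_", hash, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  write.csv(report_table(half, loo),
            file.path(out_dir, paste0("report_", hash, ".csv")),
            row.names = FALSE)
  write_config(config, file.path(out_dir, paste0("config_", hash, ".json")))
  say("done")
  invisible(list(features = tbl, ranking = ranking, trace = trace,
                 optimum = opt, half = half, loo = loo, dir = out_dir))
}
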