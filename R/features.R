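#' Feature-extraction configuration
#'
#' Collects the tunable knobs of the texture-feature stage: the grey-level
#' count G used by all matrix features (default 64), the co-occurrence
#' offsets (default distances 1 and 2 pixels), and the wavelet decomposition
#' depth (default 3, the depth that fixes the 8x8 minimum sub-image).
#'
#' @param levels Grey levels G for quantization (>= 2).
#' @param distances Integer vector of GLCM pixel distances.
#' @param wavelet_levels Wavelet decomposition depth.
#' @return A list of class `"eus_feature_config"`.
#' @export
feature_config <- function(levels = 64L, distances = c(1L, 2L),
                           wavelet_levels = 3L) {
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances),
                 wavelet_levels = as.integer(wavelet_levels)),
            class = "eus_feature_config")
}

#' The canonical 105-feature inventory
#'
#' The fixed feature inventory: 105 named features in 9 categories —
#' grey-level histogram (10), co-occurrence statistics at distances 1 and 2
#' (2 x 16 = 32, one category), run-length (11), grey-level difference
#' statistics (5), wavelet subband Shannon entropy (10), wavelet subband
#' standard deviation (10), wavelet subband energy (10), Laws 3x3 masks (9)
#' and gradient statistics (8). The order here is the canonical column
#' order of every feature table.
#'
#' @param config A [feature_config()].
#' @return A tibble with columns `feature`, `category` (105 rows).
#' @export
feature_inventory <- function(config = feature_config()) {
  wb <- wavelet_band_names(config$wavelet_levels)
  inv <- list(
    histogram = paste0("hist_", c("mean", "variance", "std", "skewness",
                                  "kurtosis", "energy", "entropy", "range",
                                  "p10", "p90")),
    glcm = as.vector(vapply(config$distances, function(d)
      paste0("glcm_d", d, "_", glcm_feature_names()), character(16))),
    glrlm = paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre",
                               "hgre", "srlge", "srhge", "lrlge", "lrhge")),
    glds = paste0("glds_", c("mean", "variance", "entropy", "asm", "contrast")),
    wavelet_entropy = paste0("wav_entropy_", wb),
    wavelet_std = paste0("wav_std_", wb),
    wavelet_energy = paste0("wav_energy_", wb),
    laws = paste0("laws_", c("l3l3", "l3e3", "l3s3", "e3l3", "e3e3", "e3s3",
                             "s3l3", "s3e3", "s3s3")),
    gradient = paste0("grad_", c("mean", "std", "skewness", "kurtosis",
                                 "energy", "entropy", "max", "edge_fraction"))
  )
  tibble(feature = unlist(inv, use.names = FALSE),
         category = rep(names(inv), lengths(inv)))
}

#' The 16 features reported as the best classifying subset
#'
#' The 16 features (from 5 categories) that the original clinical
#' evaluation identified as the optimal subset, under this package's
#' nomenclature: nine co-occurrence statistics at distance 1, three
#' histogram statistics, the wavelet entropies of `cv1`/`cv2`, the wavelet
#' standard deviation of `ca3`, and the grey-level difference variance.
#'
#' @return Character vector of 16 canonical feature names.
#' @export
reference_selected_features <- function() {
  c(paste0("glcm_d1_", c("contrast", "idm", "entropy", "sum_entropy",
                         "diff_variance", "diff_entropy", "asm",
                         "dissimilarity", "imc1")),
    "hist_std", "hist_energy", "hist_entropy",
    "wav_entropy_cv1", "wav_entropy_cv2", "wav_std_ca3",
    "glds_variance")
}

#' Extract the full texture feature vector from a sub-image
#'
#' Runs the nine feature categories on one sub-image and concatenates them
#' in canonical inventory order. The result is deterministic: the same
#' sub-image always yields the bit-identical vector.
#'
#' @param sub Grey-level sub-image matrix, at least 8x8.
#' @param config A [feature_config()].
#' @return Named numeric vector of 105 finite values, in the order of
#'   [feature_inventory()].
#' @export
extract_features <- function(sub, config = feature_config()) {
  if (nrow(sub) < 8 || ncol(sub) < 8)
    abort("sub-image must be at least 8x8")
  q <- quantize_image(sub, config$levels)
  glcm <- unlist(lapply(config$distances, function(d)
    glcm_features(compute_glcm(q, d), prefix = paste0("glcm_d", d, "_"))))
  pyr <- wavelet_pyramid(sub, config$wavelet_levels)
  out <- c(
    histogram_features(sub),
    glcm,
    glrlm_features(q),
    glds_features(q),
    wavelet_features(pyr),
    laws_features(sub),
    gradient_features(sub)
  )
  inv <- feature_inventory(config)
  out <- out[inv$feature]
  stopifnot(!anyNA(out), all(is.finite(out)))
  out
}

#' Build a labelled feature table from a cohort of images
#'
#' Maps [extract_features()] over the images of a cohort tibble (as
#' produced by [generate_cohort()], or assembled by the caller) and returns
#' the standard feature table: `case_id`, `label` (PC = 1, CP = 0), then
#' the 105 canonical feature columns.
#'
#' @param cohort Tibble with columns `case_id`, `label`, and `image` (list
#'   of grey-level matrices). If an `roi` list column is present, the
#'   analysis sub-image is first extracted with [extract_subimage()];
#'   otherwise the full image is analysed.
#' @param config A [feature_config()].
#' @return A tibble, one row per case.
#' @export
feature_table <- function(cohort, config = feature_config()) {
  stopifnot(all(c("case_id", "label", "image") %in% names(cohort)))
  rows <- purrr::pmap(cohort, function(case_id, label, image, ...) {
    dots <- list(...)
    sub <- if (!is.null(dots$roi)) extract_subimage(image, dots$roi) else image
    vec <- extract_features(sub, config)
    dplyr::bind_cols(tibble(case_id = case_id, label = as.integer(label)),
                     as_tibble(as.list(vec)))
  })
  dplyr::bind_rows(rows)
}

feature_columns <- function(table) {
  setdiff(names(table), c("case_id", "label"))
}

#' Read and write feature tables
#'
#' The on-disk interchange format: a CSV whose first column is `case_id`,
#' second `label` (PC = 1, CP = 0), followed by the canonical feature
#' columns, plus a sidecar JSON (same path with extension
#' `.categories.json`) mapping each feature to its category.
#'
#' @param table A feature table tibble.
#' @param path CSV file path.
#' @return `read_feature_table()`: the feature table tibble.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  inv <- feature_inventory()
  cats <- as.list(stats::setNames(inv$category, inv$feature))
  cats <- cats[names(cats) %in% names(table)]
  jsonlite::write_json(cats, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- as_tibble(read.csv(path, check.names = FALSE))
  stopifnot(names(tbl)[1:2] == c("case_id", "label"))
  tbl$label <- as.integer(tbl$label)
  tbl
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".categories.json")
}
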