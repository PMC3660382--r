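#' Grey-level co-occurrence matrix
#'
#' Counts ordered pixel pairs at offset `distance` along each requested
#' direction (0, 45, 90, 135 degrees), symmetrizes each directional count
#' matrix by adding its transpose, normalizes it to a joint probability
#' matrix, and averages the directional matrices. The result is the GxG
#' symmetric matrix `p(i, j)` all Haralick statistics are computed from.
#'
#' @param q A [quantize_image()] result (bin indices `0 .. G-1`).
#' @param distance Pixel offset d, at least 1 and smaller than both image
#'   dimensions.
#' @param directions Subset of `c(0, 45, 90, 135)` (degrees) to average.
#' @return Object of class `"eus_glcm"`: list with elements `p` (GxG
#'   probability matrix), `levels`, `distance`, `directions`.
#' @export
compute_glcm <- function(q, distance = 1L, directions = c(0, 45, 90, 135)) {
  G <- attr(q, "levels")
  if (is.null(G)) G <- max(q) + 1L
  d <- as.integer(distance)
  if (d < 1) abort("distance must be >= 1")
  if (d >= min(dim(q))) abort("distance must be smaller than both image dimensions")
  stopifnot(all(directions %in% c(0, 45, 90, 135)))
  offsets <- list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
  h <- nrow(q); w <- ncol(q)
  mats <- lapply(directions, function(ang) {
    off <- offsets[[as.character(ang)]]
    rs <- seq_len(h); cs <- seq_len(w)
    r1 <- rs[rs + off[1] >= 1 & rs + off[1] <= h]
    c1 <- cs[cs + off[2] >= 1 & cs + off[2] <= w]
    i <- q[r1, c1, drop = FALSE]
    j <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    counts <- matrix(tabulate(as.vector(i) * G + as.vector(j) + 1L, nbins = G * G),
                     G, G, byrow = TRUE)
    sym <- counts + t(counts)
    sym / sum(sym)
  })
  p <- Reduce(`+`, mats) / length(mats)
  structure(list(p = p, levels = G, distance = d, directions = directions),
            class = "eus_glcm")
}

#' Haralick statistics of a co-occurrence matrix
#'
#' The 16 second-order statistics computed from a normalized symmetric GLCM.
#' Grey levels are indexed 0-based throughout; logarithms are base 2 with
#' 0 log 0 := 0. Sum variance is taken about the sum average; IMC1 is 0 when
#' the marginal entropy vanishes (constant image); correlation is 0 when a
#' marginal is degenerate.
#'
#' Domain nomenclature: angular second moment is also called consistency,
#' inverse difference moment is the homogeneity / invariant-moment
#' statistic, dissimilarity is the absolute-value statistic, and difference
#' variance / difference entropy are the variance-of-differences and
#' entropy-of-differences statistics.
#'
#' @param m An `"eus_glcm"` from [compute_glcm()], or a normalized GxG
#'   probability matrix.
#' @param prefix Prefix for the feature names (default none).
#' @return Named numeric vector of 16 features: `asm`, `contrast`,
#'   `correlation`, `variance`, `idm`, `sum_average`, `sum_variance`,
#'   `sum_entropy`, `entropy`, `diff_variance`, `diff_entropy`, `imc1`,
#'   `imc2`, `dissimilarity`, `autocorrelation`, `max_prob`.
#' @export
glcm_features <- function(m, prefix = "") {
  p <- if (inherits(m, "eus_glcm")) m$p else as.matrix(m)
  if (abs(sum(p) - 1) > 1e-8) abort("GLCM must be normalized (sum to 1)")
  G <- nrow(p)
  lev <- 0:(G - 1)
  I <- matrix(lev, G, G)
  J <- t(I)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px)); sd_y <- sqrt(sum((lev - mu_y)^2 * py))

  # p_{x+y} and p_{x-y}
  psum <- as.vector(rowsum(as.vector(p), group = as.vector(I + J)))
  ks <- sort(unique(as.vector(I + J)))
  pdiff <- as.vector(rowsum(as.vector(p), group = as.vector(abs(I - J))))
  kd <- sort(unique(as.vector(abs(I - J))))

  sum_average <- sum(ks * psum)
  diff_average <- sum(kd * pdiff)

  hxy <- entropy_bits(p)
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxpy))
  hxy2 <- -sum(pxpy * log2z(pxpy))
  hx <- entropy_bits(px); hy <- entropy_bits(py)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - 2^(-2 * (hxy2 - hxy))))

  out <- c(
    asm = sum(p^2),
    contrast = sum((I - J)^2 * p),
    correlation = if (sd_x > 0 && sd_y > 0)
      (sum(I * J * p) - mu_x * mu_y) / (sd_x * sd_y) else 0,
    variance = sum((I - mu_x)^2 * p),
    idm = sum(p / (1 + (I - J)^2)),
    sum_average = sum_average,
    sum_variance = sum((ks - sum_average)^2 * psum),
    sum_entropy = entropy_bits(psum),
    entropy = hxy,
    diff_variance = sum((kd - diff_average)^2 * pdiff),
    diff_entropy = entropy_bits(pdiff),
    imc1 = imc1,
    imc2 = imc2,
    dissimilarity = sum(abs(I - J) * p),
    autocorrelation = sum(I * J * p),
    max_prob = max(p)
  )
  if (nzchar(prefix)) names(out) <- paste0(prefix, names(out))
  out
}

glcm_feature_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "diff_variance",
    "diff_entropy", "imc1", "imc2", "dissimilarity", "autocorrelation",
    "max_prob")
}
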