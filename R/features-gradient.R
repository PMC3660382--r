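#' Gradient-magnitude features
#'
#' Gradient magnitude from the 3x3 Sobel horizontal/vertical difference
#' operators (valid region), summarized by its population moments, its
#' 256-bin histogram energy and entropy (bins span `[0, max]`), the maximum
#' magnitude, and the fraction of pixels whose magnitude exceeds 10% of the
#' maximum (an edge-density surrogate). A constant image yields all
#' statistics 0.
#'
#' @param sub Sub-image matrix (at least 3x3).
#' @return Named numeric vector of 8 features prefixed `grad_`.
#' @export
gradient_features <- function(sub) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3x3_valid(sub, kx)
  gy <- conv3x3_valid(sub, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) {
    return(c(grad_mean = 0, grad_std = 0, grad_skewness = 0,
             grad_kurtosis = 0, grad_energy = 0, grad_entropy = 0,
             grad_max = 0, grad_edge_fraction = 0))
  }
  m <- pop_moments(as.vector(mag))
  idx <- pmin(floor(as.vector(mag) / mx * 256), 255)
  p <- tabulate(idx + 1L, nbins = 256L) / length(idx)
  c(
    grad_mean = unname(m["mean"]),
    grad_std = unname(m["std"]),
    grad_skewness = unname(m["skewness"]),
    grad_kurtosis = unname(m["kurtosis"]),
    grad_energy = sum(p^2),
    grad_entropy = entropy_bits(p),
    grad_max = mx,
    grad_edge_fraction = mean(as.vector(mag) > 0.1 * mx)
  )
}
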