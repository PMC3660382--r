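#' First-order (grey-level histogram) features
#'
#' Ten first-order statistics of a sub-image. Moments (mean, variance,
#' standard deviation, skewness, excess kurtosis) are computed directly on
#' the raw intensities (population moments); energy (the "consistency"
#' statistic, \eqn{\sum_k h(k)^2}) and entropy
#' (\eqn{-\sum_k h(k)\log_2 h(k)}) on the 256-bin normalized intensity
#' histogram \eqn{h}; plus the intensity range and the 10th and 90th
#' percentiles.
#'
#' A constant image yields std 0, energy 1, entropy 0, and skewness/kurtosis
#' defined as 0.
#'
#' @param sub Grey-level matrix with intensities in `[0, 255]`.
#' @return Named numeric vector of 10 features, prefixed `hist_`.
#' @export
histogram_features <- function(sub) {
  x <- as.vector(sub)
  m <- pop_moments(x)
  h <- tabulate(round(x) + 1L, nbins = 256L) / length(x)
  q <- quantile(x, c(0.1, 0.9), names = FALSE)
  c(
    hist_mean = unname(m["mean"]),
    hist_variance = unname(m["variance"]),
    hist_std = unname(m["std"]),
    hist_skewness = unname(m["skewness"]),
    hist_kurtosis = unname(m["kurtosis"]),
    hist_energy = sum(h^2),
    hist_entropy = entropy_bits(h),
    hist_range = max(x) - min(x),
    hist_p10 = q[1],
    hist_p90 = q[2]
  )
}
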