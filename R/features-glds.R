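#' Grey-level difference statistics
#'
#' Histogram of absolute grey-level differences `|q(x) - q(x + delta)|`
#' pooled over the four unit displacements (right, down, down-right,
#' down-left), normalized to a probability distribution over difference
#' values `0 .. G-1`.
#'
#' @param q A [quantize_image()] result.
#' @param displacements List of `c(drow, dcol)` displacements to pool;
#'   defaults to the four unit displacements.
#' @return Named numeric vector of 5 features prefixed `glds_`: `mean`,
#'   `variance` (the variance-of-differences statistic), `entropy`, `asm`,
#'   and `contrast` (second moment of the differences).
#' @export
glds_features <- function(q,
                          displacements = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  G <- attr(q, "levels")
  if (is.null(G)) G <- max(q) + 1L
  h <- nrow(q); w <- ncol(q)
  diffs <- unlist(lapply(displacements, function(off) {
    rs <- seq_len(h); cs <- seq_len(w)
    r1 <- rs[rs + off[1] >= 1 & rs + off[1] <= h]
    c1 <- cs[cs + off[2] >= 1 & cs + off[2] <= w]
    abs(q[r1, c1, drop = FALSE] - q[r1 + off[1], c1 + off[2], drop = FALSE])
  }))
  p <- tabulate(diffs + 1L, nbins = G) / length(diffs)
  d <- 0:(G - 1)
  mu <- sum(d * p)
  c(
    glds_mean = mu,
    glds_variance = sum((d - mu)^2 * p),
    glds_entropy = entropy_bits(p),
    glds_asm = sum(p^2),
    glds_contrast = sum(d^2 * p)
  )
}
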