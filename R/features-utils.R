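# Shared numeric helpers for the texture features.
# Conventions used throughout: logarithms are base 2 with 0*log0 := 0;
# variance/std of a sample are population moments (divide by n); skewness and
# excess kurtosis of a zero-variance sample are defined as 0.

log2z <- function(p) ifelse(p > 0, log2(p), 0)

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

pop_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean((x - m)^3) / s^3
    kurt <- mean((x - m)^4) / s^4 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = m, variance = v, std = s, skewness = skew, kurtosis = kurt)
}

# 3x3 valid-mode convolution via shifted submatrices (no padding).
conv3x3_valid <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(h >= 3, w >= 3, all(dim(k) == c(3, 3)))
  out <- matrix(0, h - 2, w - 2)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out + k[dr + 1, dc + 1] * img[dr + seq_len(h - 2), dc + seq_len(w - 2)]
  }
  out
}
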