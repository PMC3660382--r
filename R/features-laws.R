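#' Laws 3x3 texture energy features
#'
#' The nine 3x3 Laws masks are the outer products of the level, edge and
#' spot vectors L3 = (1, 2, 1), E3 = (-1, 0, 1), S3 = (-1, 2, -1). Each
#' feature is the mean absolute filter response (valid-mode convolution)
#' normalized by the mean absolute L3L3 response, which removes the overall
#' illumination level; the `l3l3` feature itself is therefore identically 1
#' and is retained as the category's reference entry.
#'
#' @param sub Sub-image matrix (at least 3x3).
#' @return Named numeric vector of 9 features prefixed `laws_`
#'   (`l3l3`, `l3e3`, ..., `s3s3`; first factor filters rows, second
#'   columns).
#' @export
laws_features <- function(sub) {
  v <- list(l3 = c(1, 2, 1), e3 = c(-1, 0, 1), s3 = c(-1, 2, -1))
  norm <- mean(abs(conv3x3_valid(sub, outer(v$l3, v$l3))))
  out <- numeric(9)
  nms <- character(9)
  k <- 1
  for (a in names(v)) {
    for (b in names(v)) {
      resp <- mean(abs(conv3x3_valid(sub, outer(v[[a]], v[[b]]))))
      out[k] <- if (norm > 0) resp / norm else 0
      nms[k] <- paste0("laws_", a, b)
      k <- k + 1
    }
  }
  stats::setNames(out, nms)
}
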