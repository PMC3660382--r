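#' Grey-level run-length features
#'
#' Maximal runs of equal grey level are enumerated along each of the four
#' directions (0, 45, 90, 135 degrees); the 11 standard run-length
#' statistics are computed per direction and averaged. Grey levels enter the
#' low/high grey-level emphasis statistics 1-based (level index + 1) so the
#' weights are well defined at level 0.
#'
#' @param q A [quantize_image()] result.
#' @param directions Subset of `c(0, 45, 90, 135)` to average.
#' @return Named numeric vector of 11 features prefixed `glrlm_`: short/long
#'   run emphasis (`sre`, `lre`), grey-level and run-length non-uniformity
#'   (`gln`, `rln`), run percentage (`rp`), low/high grey-level run emphasis
#'   (`lgre`, `hgre`), and the four joint emphases (`srlge`, `srhge`,
#'   `lrlge`, `lrhge`).
#' @export
glrlm_features <- function(q, directions = c(0, 45, 90, 135)) {
  stopifnot(all(directions %in% c(0, 45, 90, 135)))
  np <- length(q)
  per_dir <- lapply(directions, function(ang) {
    runs <- runs_along(q, ang)
    g <- runs$level + 1  # 1-based grey value
    l <- runs$length
    nr <- length(l)
    c(
      glrlm_sre = sum(1 / l^2) / nr,
      glrlm_lre = sum(l^2) / nr,
      glrlm_gln = sum(tapply(rep(1, nr), g, sum)^2) / nr,
      glrlm_rln = sum(tapply(rep(1, nr), l, sum)^2) / nr,
      glrlm_rp = nr / np,
      glrlm_lgre = sum(1 / g^2) / nr,
      glrlm_hgre = sum(g^2) / nr,
      glrlm_srlge = sum(1 / (l^2 * g^2)) / nr,
      glrlm_srhge = sum(g^2 / l^2) / nr,
      glrlm_lrlge = sum(l^2 / g^2) / nr,
      glrlm_lrhge = sum(l^2 * g^2) / nr
    )
  })
  Reduce(`+`, per_dir) / length(per_dir)
}

# All maximal runs of constant value along one direction.
# Returns data.frame(level, length).
runs_along <- function(q, angle) {
  lines <- switch(as.character(angle),
    `0` = split(q, row(q)),
    `90` = split(q, col(q)),
    `45` = split(q, row(q) + col(q)),       # anti-diagonals
    `135` = split(q, row(q) - col(q))       # diagonals
  )
  # split() on row()/col() keys preserves within-line pixel order for rows,
  # columns and diagonals of a matrix stored column-major
  lv <- ll <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    r <- rle(as.vector(lines[[k]]))
    lv[[k]] <- r$values
    ll[[k]] <- r$lengths
  }
  data.frame(level = unlist(lv), length = unlist(ll))
}
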