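# Deterministic image fixtures, built in code.

make_checkerboard <- function(h = 8, w = 8, values = c(0, 255)) {
  i <- matrix(seq_len(h) - 1, h, w)
  j <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  matrix(values[(i + j) %% 2 + 1], h, w)
}

make_ramp <- function(h = 16, w = 16, horizontal = TRUE) {
  if (horizontal) {
    matrix(rep(round(seq(0, 255, length.out = w)), each = h), h, w)
  } else {
    matrix(rep(round(seq(0, 255, length.out = h)), times = w), h, w)
  }
}

make_random_image <- function(h = 8, w = 8, seed = 1, levels = 256) {
  withr::with_seed(seed, matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w))
}

make_step_edge <- function(h = 16, w = 16, edge_col = 8) {
  img <- matrix(0, h, w)
  img[, edge_col:w] <- 200
  img
}

# polygon approximating a circle (0-based row/col center and radius)
circle_polygon <- function(center, radius, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = center[1] + radius * sin(th), col = center[2] + radius * cos(th))
}

# rectangle polygon covering rows r0..r1, cols c0..c1 inclusive (0-based)
rect_polygon <- function(r0, r1, c0, c1) {
  cbind(row = c(r0, r0, r1, r1), col = c(c0, c1, c1, c0))
}

write_roi_file <- function(vertices, path) {
  writeLines(c("# ROI vertex list (row,col)",
               sprintf("%g,%g", vertices[, 1], vertices[, 2])), path)
  path
}
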