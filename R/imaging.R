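#' Grey-scale still images
#'
#' An EUS still image is represented as a plain integer matrix with
#' intensities in `[0, 255]` (rows = image rows). [read_gray_image()] reads
#' 8-bit grayscale BMP (the format echoendoscopes save to) and PNG files;
#' RGB files are accepted only when all three channels are identical, i.e.
#' a grayscale image stored in an RGB container. [write_gray_image()] writes
#' either format, chosen from the file extension.
#'
#' @param path File path; extension `.bmp` or `.png` (case-insensitive).
#' @return `read_gray_image()`: an integer matrix in `[0, 255]`.
#' @examples
#' img <- matrix(0:255, 16, 16)
#' f <- tempfile(fileext = ".png")
#' write_gray_image(img, f)
#' identical(read_gray_image(f), img)
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    bmp = read_bmp_gray(path),
    png = read_png_gray(path),
    abort(paste0("unsupported image format: .", ext, " (expected BMP or PNG)"))
  )
  validate_gray_image(img)
  img
}

#' @param image Integer matrix in `[0, 255]`.
#' @rdname read_gray_image
#' @export
write_gray_image <- function(image, path) {
  validate_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    bmp = write_bmp_gray(image, path),
    png = png::writePNG(image / 255, path),
    abort(paste0("unsupported image format: .", ext))
  )
  invisible(path)
}

validate_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    abort("image must be a numeric matrix")
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    abort("image intensities must lie in [0, 255]")
  invisible(image)
}

read_png_gray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    rgb <- a[, , seq_len(min(nch, 3L)), drop = FALSE]
    if (dim(rgb)[3] > 1L) {
      eq <- max(abs(rgb[, , 1] - rgb[, , 2])) == 0 &&
        max(abs(rgb[, , 1] - rgb[, , 3])) == 0
      if (!eq)
        abort("RGB image is not grayscale: channels differ (color overlay?)")
    }
    a <- rgb[, , 1]
  }
  out <- round(a * 255)
  storage.mode(out) <- "integer"
  out
}

# Minimal uncompressed BMP support: 8-bit palette (grayscale palette) and
# 24-bit BGR where B=G=R. Rows are stored bottom-up and padded to 4 bytes.
read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    abort("not a BMP file")
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * 256^(0:1))
  offset <- u32(11)
  width <- u32(19); height_raw <- u32(23)
  topdown <- height_raw > 2^31
  height <- if (topdown) 2^32 - height_raw else height_raw
  bpp <- u16(29); compression <- u32(31)
  if (compression != 0) abort("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L)) abort("only 8-bit and 24-bit BMP supported")
  bytes_pp <- bpp / 8
  stride <- 4 * ceiling(width * bytes_pp / 4)
  img <- matrix(0L, height, width)
  for (r in seq_len(height)) {
    row0 <- offset + (r - 1) * stride      # stored row index r (from file order)
    line <- as.integer(raw[row0 + seq_len(width * bytes_pp)])
    vals <- if (bpp == 8L) line else {
      b <- line[seq(1, length(line), 3)]
      g <- line[seq(2, length(line), 3)]
      rr <- line[seq(3, length(line), 3)]
      if (any(b != g) || any(b != rr))
        abort("RGB BMP is not grayscale: channels differ")
      b
    }
    target <- if (topdown) r else height - r + 1
    img[target, ] <- vals
  }
  if (bpp == 8L) {
    # map through the palette (assumed grayscale; verify)
    pal0 <- 55 + 4 * (0:255)
    pal <- vapply(0:255, function(k) as.integer(raw[55 + 4 * k]), integer(1))
    palg <- vapply(0:255, function(k) as.integer(raw[56 + 4 * k]), integer(1))
    palr <- vapply(0:255, function(k) as.integer(raw[57 + 4 * k]), integer(1))
    if (any(pal != palg) || any(pal != palr))
      abort("BMP palette is not grayscale")
    img[] <- pal[img + 1L]
  }
  img
}

write_bmp_gray <- function(image, path) {
  image <- round(image)
  h <- nrow(image); w <- ncol(image)
  stride <- 4 * ceiling(w / 4)
  u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216 %% 256))
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
  pal <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, rep(0, 256))))
  data_size <- stride * h
  off <- 54 + 1024
  header <- c(
    charToRaw("BM"), u32(off + data_size), u16(0), u16(0), u32(off),
    u32(40), u32(w), u32(h), u16(1), u16(8), u32(0), u32(data_size),
    u32(2835), u32(2835), u32(256), u32(0)
  )
  body <- raw(data_size)
  for (r in seq_len(h)) {
    # bottom-up row order
    row <- as.raw(image[h - r + 1, ])
    body[(r - 1) * stride + seq_len(w)] <- row
  }
  writeBin(c(header, pal, body), path)
  invisible(path)
}

#' Read a region-of-interest polygon
#'
#' ROI files are plain text with one `row,col` vertex per line (0-based pixel
#' coordinates, polygon closed implicitly); blank lines and `#` comments are
#' ignored. The polygon is validated against the image: at least 3 vertices,
#' all inside the image bounds, and simple (no two non-adjacent edges
#' intersect).
#'
#' @param path ROI text file.
#' @param image The [read_gray_image()] matrix the ROI was drawn on.
#' @return A numeric matrix with columns `row`, `col` (0-based vertices),
#'   class `"eus_roi"`.
#' @export
read_roi <- function(path, image) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",")
  if (any(lengths(parts) != 2L)) abort("ROI file lines must be 'row,col'")
  v <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("row", "col")))
  roi_polygon(v, dim(image))
}

#' @param vertices Numeric matrix of 0-based `(row, col)` vertices.
#' @param image_dim Integer `c(height, width)`.
#' @rdname read_roi
#' @export
roi_polygon <- function(vertices, image_dim) {
  v <- as.matrix(vertices)
  if (anyNA(v)) abort("ROI vertices contain NA")
  if (nrow(v) < 3L) abort("ROI polygon needs at least 3 vertices")
  h <- image_dim[1]; w <- image_dim[2]
  bad <- v[, 1] < 0 | v[, 1] > h - 1 | v[, 2] < 0 | v[, 2] > w - 1
  if (any(bad))
    abort(sprintf("ROI vertex out of image bounds: (%g, %g)",
                  v[which(bad)[1], 1], v[which(bad)[1], 2]))
  if (polygon_self_intersects(v)) abort("ROI polygon is self-intersecting")
  colnames(v) <- c("row", "col")
  structure(v, class = c("eus_roi", class(v)), image_dim = as.integer(image_dim))
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # r1 c1 r2 c2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the ROI if its center (integer 0-based coordinates)
#' lies inside the polygon under the even-odd rule; centers exactly on the
#' boundary count as inside.
#'
#' @param roi An [roi_polygon()].
#' @param image_dim `c(height, width)`; defaults to the dim the ROI was
#'   validated against.
#' @return Logical matrix of the image size.
#' @export
rasterize_roi <- function(roi, image_dim = attr(roi, "image_dim")) {
  h <- image_dim[1]; w <- image_dim[2]
  vr <- roi[, 1]; vc <- roi[, 2]
  n <- length(vr)
  pts_r <- rep(0:(h - 1), times = w)
  pts_c <- rep(0:(w - 1), each = h)
  inside <- rep(FALSE, h * w)
  on_edge <- rep(FALSE, h * w)
  j <- n
  for (i in seq_len(n)) {
    ri <- vr[i]; ci <- vc[i]; rj <- vr[j]; cj <- vc[j]
    crosses <- ((ci > pts_c) != (cj > pts_c)) &
      (pts_r < (rj - ri) * (pts_c - ci) / (cj - ci) + ri)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # point-on-segment: collinear and within bounding box
    det <- (rj - ri) * (pts_c - ci) - (cj - ci) * (pts_r - ri)
    on <- det == 0 &
      pts_r >= pmin(ri, rj) & pts_r <= pmax(ri, rj) &
      pts_c >= pmin(ci, cj) & pts_c <= pmax(ci, cj)
    on_edge <- on_edge | on
    j <- i
  }
  matrix(inside | on_edge, h, w)
}

#' Extract the largest rectangular sub-image inside an ROI
#'
#' Finds the maximum-area axis-aligned rectangle whose pixels all lie inside
#' the rasterized ROI mask (ties broken towards larger height, then smaller
#' origin row, then smaller origin column) and crops it from the image. The
#' rectangle must be at least 8x8 pixels — the minimum the 3-level wavelet
#' decomposition needs.
#'
#' @param image Grey-level matrix.
#' @param roi An [roi_polygon()], or a logical mask matrix of the image size.
#' @return The cropped matrix with attribute `origin`, the 0-based
#'   `(row, col)` of its top-left corner in the parent image.
#' @export
extract_subimage <- function(image, roi) {
  validate_gray_image(image)
  mask <- if (is.logical(roi)) roi else rasterize_roi(roi, dim(image))
  stopifnot(identical(dim(mask), dim(image)))
  rect <- largest_rectangle(mask)
  if (rect$area == 0 || rect$h < 8 || rect$w < 8)
    abort("ROI too small: no 8x8 rectangle fits inside it")
  sub <- image[rect$r0 + seq_len(rect$h), rect$c0 + seq_len(rect$w), drop = FALSE]
  attr(sub, "origin") <- c(row = rect$r0, col = rect$c0)
  sub
}

# Largest all-TRUE axis-aligned rectangle in a logical mask.
# Row-by-row histogram of column heights with a monotone stack; every maximal
# rectangle is enumerated once, so the deterministic tie-break (larger area,
# then larger height, then smaller 0-based origin row, then column) is exact.
largest_rectangle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  heights <- integer(W)
  best <- list(area = 0L, h = 0L, w = 0L, r0 = 0L, c0 = 0L)
  better <- function(area, hh, r0, c0) {
    if (area != best$area) return(area > best$area)
    if (hh != best$h) return(hh > best$h)
    if (r0 != best$r0) return(r0 < best$r0)
    c0 < best$c0
  }
  for (r in seq_len(H)) {
    heights <- ifelse(mask[r, ], heights + 1L, 0L)
    stack_pos <- integer(W + 1); stack_h <- integer(W + 1); top <- 0L
    for (c in seq_len(W + 1)) {
      cur <- if (c <= W) heights[c] else 0L
      start <- c
      while (top > 0L && stack_h[top] > cur) {
        hh <- stack_h[top]; left <- stack_pos[top]; top <- top - 1L
        area <- hh * (c - left)
        r0 <- r - hh; c0 <- left - 1L           # 0-based origin
        if (hh > 0L && better(area, hh, r0, c0))
          best <- list(area = area, h = hh, w = c - left, r0 = r0, c0 = c0)
        start <- left
      }
      if (top == 0L || stack_h[top] < cur) {
        top <- top + 1L; stack_pos[top] <- start; stack_h[top] <- cur
      }
    }
  }
  best
}

#' Quantize a sub-image to G grey levels
#'
#' Min-max linear binning over the sub-image's own intensity range into
#' `levels` equal-width bins (bin indices `0 .. levels-1`). A constant image
#' maps entirely to bin 0. The mapping is monotone in intensity.
#'
#' @param sub Grey-level matrix (a sub-image).
#' @param levels Number of grey levels G, at least 2. Default 64, the level
#'   count used by all co-occurrence/run-length features.
#' @return Integer matrix of bin indices with attribute `levels`.
#' @export
quantize_image <- function(sub, levels = 64L) {
  if (levels < 2) abort("levels must be >= 2")
  mn <- min(sub); mx <- max(sub)
  if (mx == mn) {
    q <- matrix(0L, nrow(sub), ncol(sub))
  } else {
    q <- floor((sub - mn) / (mx - mn) * levels)
    q[q == levels] <- levels - 1
    storage.mode(q) <- "integer"
  }
  attr(q, "levels") <- as.integer(levels)
  q
}
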