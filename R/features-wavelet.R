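# Daubechies-4 analysis/synthesis filter bank (8 taps). Standard published
# coefficients; dec_lo is the lowpass analysis filter in convolution order.
DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)
DB4_REC_LO <- rev(DB4_DEC_LO)
DB4_REC_HI <- rev(DB4_DEC_HI)

# Half-point symmetric extension of x by k samples on both sides
# (edge sample repeated: ... x3 x2 x1 | x1 x2 ... xn | xn xn-1 ...).
sym_extend <- function(x, k) {
  n <- length(x)
  i <- seq(-k, n + k - 1)
  idx <- i %% (2L * n)
  x[ifelse(idx < n, idx + 1L, 2L * n - idx)]
}

# Single-level 1-D analysis: symmetric extension, convolution, dyadic
# downsampling. Output length floor((n + L - 1) / 2).
dwt1 <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  ext <- sym_extend(x, L - 1L)
  cv <- convolve(ext, rev(filt), type = "open")
  cv[seq(L + 1, by = 2, length.out = (n + L - 1) %/% 2)]
}

# Single-level 1-D synthesis; exact inverse of dwt1 (crops to length n).
idwt1 <- function(a, d, n) {
  L <- length(DB4_REC_LO)
  up <- function(cf) {
    u <- numeric(2 * length(cf))
    u[seq(1, by = 2, length.out = length(cf))] <- cf
    u
  }
  y <- convolve(up(a), rev(DB4_REC_LO), type = "open") +
    convolve(up(d), rev(DB4_REC_HI), type = "open")
  y[seq(L - 1, length.out = n)]
}

dwt2 <- function(mat) {
  # transform rows (along width), then columns (along height)
  lo <- t(apply(mat, 1, dwt1, filt = DB4_DEC_LO))
  hi <- t(apply(mat, 1, dwt1, filt = DB4_DEC_HI))
  list(
    ca = apply(lo, 2, dwt1, filt = DB4_DEC_LO),
    ch = apply(lo, 2, dwt1, filt = DB4_DEC_HI),  # highpass rows: horizontal structure
    cv = apply(hi, 2, dwt1, filt = DB4_DEC_LO),  # highpass cols: vertical structure
    cd = apply(hi, 2, dwt1, filt = DB4_DEC_HI)
  )
}

idwt2 <- function(ca, ch, cv, cd, target_dim) {
  h <- target_dim[1]; w <- target_dim[2]
  col_inv <- function(a, d) {
    vapply(seq_len(ncol(a)), function(j) idwt1(a[, j], d[, j], h), numeric(h))
  }
  lo <- col_inv(ca, ch)
  hi <- col_inv(cv, cd)
  out <- t(vapply(seq_len(h), function(i) idwt1(lo[i, ], hi[i, ], w), numeric(w)))
  out
}

#' Three-level 2-D wavelet decomposition
#'
#' Separable 2-D discrete wavelet transform with the Daubechies-4 wavelet
#' and half-point symmetric boundary extension, iterated 3 times on the
#' approximation band. Yields the 10 subbands `ch1, cv1, cd1, ch2, cv2,
#' cd2, ch3, cv3, cd3, ca3`, where `ch` = horizontal detail (highpass along
#' rows), `cv` = vertical detail, `cd` = diagonal detail and `ca3` the
#' final approximation.
#'
#' @param sub Sub-image matrix, at least 8x8.
#' @param levels Decomposition depth (default 3).
#' @return Object of class `"eus_wavelet"`: list with `subbands` (named list
#'   of coefficient matrices), `dims` (per-level input dimensions, needed for
#'   exact reconstruction), `wavelet`, `levels`.
#' @seealso [wavelet_reconstruct()] for the exact inverse.
#' @export
wavelet_pyramid <- function(sub, levels = 3L) {
  if (nrow(sub) < 8 || ncol(sub) < 8)
    abort("sub-image must be at least 8x8 for the wavelet decomposition")
  subbands <- list()
  dims <- vector("list", levels)
  cur <- sub
  for (lv in seq_len(levels)) {
    dims[[lv]] <- dim(cur)
    b <- dwt2(cur)
    subbands[[paste0("ch", lv)]] <- b$ch
    subbands[[paste0("cv", lv)]] <- b$cv
    subbands[[paste0("cd", lv)]] <- b$cd
    cur <- b$ca
  }
  subbands[[paste0("ca", levels)]] <- cur
  structure(list(subbands = subbands, dims = dims, wavelet = "db4",
                 levels = levels),
            class = "eus_wavelet")
}

#' @param pyramid An `"eus_wavelet"` object.
#' @rdname wavelet_pyramid
#' @return `wavelet_reconstruct()`: the reconstructed matrix (equal to the
#'   input up to floating-point round-off).
#' @export
wavelet_reconstruct <- function(pyramid) {
  lv <- pyramid$levels
  ca <- pyramid$subbands[[paste0("ca", lv)]]
  for (l in rev(seq_len(lv))) {
    ca <- idwt2(ca,
                pyramid$subbands[[paste0("ch", l)]],
                pyramid$subbands[[paste0("cv", l)]],
                pyramid$subbands[[paste0("cd", l)]],
                pyramid$dims[[l]])
  }
  ca
}

#' Wavelet subband statistics
#'
#' Three statistics per subband, over the 10 subbands of the 3-level
#' pyramid: the Shannon entropy of the normalized coefficient-energy
#' distribution \eqn{q_k = c_k^2 / \sum c^2}, \eqn{H = -\sum q_k \log_2
#' q_k}; the (population) standard deviation of the coefficients; and the
#' mean squared coefficient (energy). An all-zero subband has entropy and
#' standard deviation 0 by convention.
#'
#' @param pyramid An `"eus_wavelet"` from [wavelet_pyramid()].
#' @return Named numeric vector of 30 features: `wav_entropy_<band>`,
#'   `wav_std_<band>`, `wav_energy_<band>` for each subband.
#' @export
wavelet_features <- function(pyramid) {
  bands <- pyramid$subbands
  ent <- vapply(bands, function(b) {
    e <- as.vector(b)^2
    tot <- sum(e)
    if (tot == 0) return(0)
    entropy_bits(e / tot)
  }, numeric(1))
  std <- vapply(bands, function(b) {
    v <- as.vector(b)
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  energy <- vapply(bands, function(b) mean(as.vector(b)^2), numeric(1))
  c(
    stats::setNames(ent, paste0("wav_entropy_", names(bands))),
    stats::setNames(std, paste0("wav_std_", names(bands))),
    stats::setNames(energy, paste0("wav_energy_", names(bands)))
  )
}

wavelet_band_names <- function(levels = 3L) {
  c(as.vector(vapply(seq_len(levels),
                     function(l) paste0(c("ch", "cv", "cd"), l),
                     character(3))),
    paste0("ca", levels))
}
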