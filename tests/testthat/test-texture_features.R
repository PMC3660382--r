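test_that("histogram features: closed forms and brute-force moments", {
  const <- histogram_features(matrix(97, 16, 16))
  expect_equal(const[["hist_std"]], 0)
  expect_equal(const[["hist_energy"]], 1)
  expect_equal(const[["hist_entropy"]], 0)
  expect_equal(const[["hist_skewness"]], 0)
  expect_equal(const[["hist_kurtosis"]], 0)

  half <- histogram_features(make_checkerboard(8, 8))  # half 0s, half 255s
  expect_equal(half[["hist_entropy"]], 1)
  expect_equal(half[["hist_energy"]], 0.5)
  expect_equal(half[["hist_range"]], 255)

  img <- make_random_image(32, 32, seed = 7)
  got <- histogram_features(img)
  want <- oracle_moments(as.vector(img))
  for (m in names(want))
    expect_equal(got[[paste0("hist_", m)]], want[[m]], tolerance = 1e-12)
})

test_that("GLCM construction matches pair enumeration and its closed forms", {
  # constant image: all mass at (0,0)
  qc <- quantize_image(matrix(5, 2, 2), 4)
  pc <- compute_glcm(qc, 1)$p
  expect_equal(pc[1, 1], 1)
  expect_equal(sum(pc), 1)

  # checkerboard, 0-degree matrix only: all neighbours differ
  qb <- quantize_image(make_checkerboard(8, 8), 2)
  pb <- compute_glcm(qb, 1, directions = 0)$p
  expect_equal(pb[1, 2], 0.5)
  expect_equal(pb[2, 1], 0.5)
  expect_equal(pb[1, 1] + pb[2, 2], 0)

  for (seed in 1:10) {
    q <- make_random_image(8, 8, seed = seed, levels = 8)
    attr(q, "levels") <- 8L
    got <- compute_glcm(q, 1)$p
    expect_equal(got, oracle_glcm(q, 1), tolerance = 1e-12,
                 label = paste("seed", seed))
  }
})

test_that("GLCM distance must fit inside the image", {
  q <- quantize_image(make_random_image(6, 6, seed = 1), 8)
  expect_error(compute_glcm(q, 6), "smaller than both image dimensions")
  expect_error(compute_glcm(q, 0), "distance")
})

test_that("all 16 Haralick statistics agree with the textbook oracle", {
  # single-cell matrix (constant image)
  f1 <- glcm_features(compute_glcm(quantize_image(matrix(3, 4, 4), 8), 1))
  expect_equal(f1[["asm"]], 1)
  expect_equal(f1[["contrast"]], 0)
  expect_equal(f1[["entropy"]], 0)
  expect_equal(f1[["dissimilarity"]], 0)
  expect_equal(f1[["max_prob"]], 1)

  # checkerboard 0-degree matrix: contrast 1, dissimilarity 1, ASM 0.5
  qb <- quantize_image(make_checkerboard(8, 8), 2)
  fb <- glcm_features(compute_glcm(qb, 1, directions = 0))
  expect_equal(fb[["contrast"]], 1)
  expect_equal(fb[["dissimilarity"]], 1)
  expect_equal(fb[["asm"]], 0.5)

  for (seed in 1:10) {
    q <- make_random_image(8, 8, seed = 100 + seed, levels = 8)
    attr(q, "levels") <- 8L
    p <- compute_glcm(q, 1)$p
    got <- glcm_features(p)
    want <- oracle_glcm_features(p)
    expect_equal(got[names(want)], want, tolerance = 1e-10,
                 label = paste("seed", seed))
  }
})

test_that("GLCM invariant properties hold on random inputs", {
  for (seed in 1:10) {
    q <- make_random_image(10, 12, seed = 200 + seed, levels = 16)
    attr(q, "levels") <- 16L
    g <- compute_glcm(q, sample(1:2, 1))
    expect_equal(g$p, t(g$p), tolerance = 1e-14)           # symmetry
    expect_equal(sum(g$p), 1, tolerance = 1e-12)           # normalization
    f <- glcm_features(g)
    expect_gte(f[["contrast"]], 0)
    expect_true(f[["asm"]] > 0 && f[["asm"]] <= 1)
    expect_true(f[["entropy"]] >= 0 && f[["entropy"]] <= 2 * log2(16))
  }
})

test_that("run-length features: hand-computed runs and oracle equivalence", {
  # single run of length 4 along 0 degrees
  q1 <- matrix(5L, 1, 4)
  attr(q1, "levels") <- 8L
  f1 <- glrlm_features(q1, directions = 0)
  expect_equal(f1[["glrlm_lre"]], 16)
  expect_equal(f1[["glrlm_sre"]], 1 / 16)
  expect_equal(f1[["glrlm_rp"]], 1 / 4)

  # checkerboard: every run has length 1 along the axial directions
  # (its diagonals are constant, so those directions see long runs)
  qb <- quantize_image(make_checkerboard(8, 8), 2)
  fb <- glrlm_features(qb, directions = c(0, 90))
  expect_equal(fb[["glrlm_lre"]], 1)
  expect_equal(fb[["glrlm_sre"]], 1)

  for (seed in 1:6) {
    q <- make_random_image(8, 8, seed = 300 + seed, levels = 4)
    attr(q, "levels") <- 4L
    expect_equal(glrlm_features(q), oracle_glrlm_features(q),
                 tolerance = 1e-12, label = paste("seed", seed))
  }
})

test_that("grey-level difference statistics match the difference histogram", {
  qc <- quantize_image(matrix(42, 8, 8), 16)
  fc <- glds_features(qc)
  expect_equal(fc[["glds_mean"]], 0)
  expect_equal(fc[["glds_variance"]], 0)
  expect_equal(fc[["glds_asm"]], 1)

  # checkerboard with horizontal displacement only: every difference is 1
  qb <- quantize_image(make_checkerboard(8, 8), 2)
  fb <- glds_features(qb, displacements = list(c(0, 1)))
  expect_equal(fb[["glds_mean"]], 1)
  expect_equal(fb[["glds_variance"]], 0)

  for (seed in 1:6) {
    q <- make_random_image(8, 8, seed = 400 + seed, levels = 8)
    attr(q, "levels") <- 8L
    expect_equal(glds_features(q), oracle_glds_features(q),
                 tolerance = 1e-12, label = paste("seed", seed))
  }
})

test_that("wavelet pyramid has the documented structure", {
  p <- wavelet_pyramid(make_random_image(64, 64, seed = 9))
  expect_named(p$subbands, c("ch1", "cv1", "cd1", "ch2", "cv2", "cd2",
                             "ch3", "cv3", "cd3", "ca3"))
  expect_equal(dim(p$subbands$ch1), c(35, 35))  # floor((64+7)/2)
  expect_equal(dim(p$subbands$ca3), c(14, 14))  # 35 -> 21 -> 14 with padding
  expect_error(wavelet_pyramid(matrix(0, 7, 16)), "8x8")
})

test_that("constant images give vanishing detail coefficients", {
  p <- wavelet_pyramid(matrix(120, 32, 32))
  for (b in setdiff(names(p$subbands), "ca3"))
    expect_lt(max(abs(p$subbands[[b]])), 1e-8)
  expect_lt(diff(range(p$subbands$ca3)), 1e-8)
})

test_that("wavelet decomposition inverts exactly", {
  for (d in list(c(8, 8), c(16, 24), c(33, 47), c(64, 64))) {
    img <- make_random_image(d[1], d[2], seed = sum(d))
    p <- wavelet_pyramid(img)
    expect_lt(max(abs(wavelet_reconstruct(p) - img)), 1e-8,
              label = paste(d, collapse = "x"))
  }
})

test_that("level-1 subbands agree with independently computed reference values", {
  # Frozen from an independent separable db4 implementation (half-point
  # symmetric extension) on the fixture x = (7 i + 13 j) mod 17, 0-based.
  i <- matrix(0:7, 8, 8)
  x <- (i * 7 + t(i) * 13) %% 17
  b <- eustex:::dwt2(x)
  expect_equal(sum(b$ca), 772.7490094287122, tolerance = 1e-10)
  expect_equal(sum(abs(b$ch)), 263.6980994416353, tolerance = 1e-10)
  expect_equal(sum(abs(b$cv)), 175.25876576088376, tolerance = 1e-10)
  expect_equal(sum(abs(b$cd)), 103.2988986182171, tolerance = 1e-10)
  expect_equal(b$ca[1, 1:3],
               c(18.55143664670696, 14.514359757637981, 12.446113525334848),
               tolerance = 1e-10)
  expect_equal(b$ch[1, 1:3],
               c(-1.098377459814631, -1.039566437277621, 1.424687378061337),
               tolerance = 1e-10)
})

test_that("wavelet subband statistics: uniform-energy and single-coefficient forms", {
  p <- wavelet_pyramid(make_random_image(32, 32, seed = 5))
  # closed form: n equal-magnitude coefficients -> entropy log2 n
  p$subbands$ch1 <- matrix(c(2, -2, 2, -2, 2, -2, 2, -2), 2, 4)
  p$subbands$cv1 <- matrix(c(3, 0, 0, 0), 2, 2)  # single nonzero -> 0 bits
  f <- wavelet_features(p)
  expect_equal(f[["wav_entropy_ch1"]], 3)
  expect_equal(f[["wav_entropy_cv1"]], 0)
  expect_equal(f[["wav_std_ch1"]], 2)
  expect_equal(f[["wav_energy_ch1"]], 4)

  # direct-formula oracle on a random subband
  b <- p$subbands$cd2
  q <- as.vector(b)^2 / sum(b^2)
  expect_equal(f[["wav_entropy_cd2"]], -sum(q[q > 0] * log2(q[q > 0])),
               tolerance = 1e-12)
  expect_equal(f[["wav_std_cd2"]], sqrt(mean((b - mean(b))^2)),
               tolerance = 1e-12)
})

test_that("Laws masks: zero-sum kernels, directionality, convolution oracle", {
  fc <- laws_features(matrix(80, 16, 16))
  expect_equal(fc[["laws_l3l3"]], 1)
  for (n in c("l3e3", "l3s3", "e3l3", "e3e3", "e3s3", "s3l3", "s3e3", "s3s3"))
    expect_equal(fc[[paste0("laws_", n)]], 0)

  # horizontal ramp: column-edge mask responds, row-edge mask does not
  ramp <- make_ramp(16, 16, horizontal = TRUE)
  fr <- laws_features(ramp)
  expect_gt(fr[["laws_l3e3"]], 0.01)   # E3 along columns sees the gradient
  expect_lt(fr[["laws_e3l3"]], 1e-10)  # E3 along rows sees nothing

  img <- make_random_image(12, 12, seed = 21)
  got <- laws_features(img)
  l3 <- c(1, 2, 1); e3 <- c(-1, 0, 1)
  norm <- mean(abs(oracle_conv3x3(img, outer(l3, l3))))
  expect_equal(got[["laws_l3e3"]],
               mean(abs(oracle_conv3x3(img, outer(l3, e3)))) / norm,
               tolerance = 1e-12)
})

test_that("gradient features: degenerate forms, step edge, oracle", {
  fc <- gradient_features(matrix(33, 16, 16))
  expect_true(all(fc == 0))

  # vertical step edge: response is confined to the edge columns
  step <- make_step_edge(16, 16, edge_col = 8)
  fs <- gradient_features(step)
  expect_gt(fs[["grad_max"]], 0)
  # Sobel valid region is 14 columns; the 3px-wide edge response band
  # occupies 2/14 of them at magnitude > 10% of max
  expect_equal(fs[["grad_edge_fraction"]], 2 / 14, tolerance = 1e-12)

  img <- make_random_image(12, 12, seed = 31)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  mag <- sqrt(oracle_conv3x3(img, kx)^2 + oracle_conv3x3(img, t(kx))^2)
  got <- gradient_features(img)
  expect_equal(got[["grad_mean"]], mean(mag), tolerance = 1e-12)
  expect_equal(got[["grad_max"]], max(mag), tolerance = 1e-12)
})

test_that("extract_features returns the canonical 105-feature vector", {
  inv <- feature_inventory()
  expect_equal(nrow(inv), 105)
  expect_equal(length(unique(inv$category)), 9)
  expect_true(all(reference_selected_features() %in% inv$feature))
  expect_equal(length(reference_selected_features()), 16)

  img <- make_random_image(32, 32, seed = 13)
  v <- extract_features(img)
  expect_named(v, inv$feature)
  expect_true(all(is.finite(v)))

  # degenerate input: still 105 finite values
  vc <- extract_features(matrix(50, 16, 16))
  expect_true(all(is.finite(vc)))

  # determinism: bit-identical on repeat
  expect_identical(v, extract_features(img))
})

test_that("additive noise monotonically raises contrast and gradient mean", {
  # Per-sub-image min-max quantization makes the matrix features invariant
  # to a pure rescaling of the noise, so the contrast response is measured
  # on a fixed 0-255 binning (64 levels of width 4); the gradient mean acts
  # on raw intensities and comes straight from the feature vector.
  base <- matrix(100, 32, 32)
  vals <- purrr::map_dfr(c(5, 15, 40), function(amp) {
    noisy <- withr::with_seed(99, base + matrix(rnorm(32 * 32, sd = amp), 32, 32))
    noisy <- pmin(pmax(round(noisy), 0), 255)
    q <- matrix(as.integer(noisy %/% 4), 32, 32)
    attr(q, "levels") <- 64L
    tibble::tibble(amp = amp,
                   contrast = glcm_features(compute_glcm(q, 1))[["contrast"]],
                   grad = extract_features(noisy)[["grad_mean"]])
  })
  expect_true(all(diff(vals$contrast) > 0))
  expect_true(all(diff(vals$grad) > 0))
})
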