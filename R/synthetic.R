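#' Speckle texture class parameters
#'
#' Knobs of the synthetic ultrasound-like texture generator. Speckle is the
#' magnitude of a complex white-noise field smoothed by a Gaussian kernel:
#' `correlation_length` (pixels) sets the speckle grain size,
#' `echogenicity` the mean intensity (0-255), `focus_rate` the expected
#' number of bright foci per 1,000 px^2 (emulating hyperechoic foci such
#' as the calcifications of chronic pancreatitis), `focus_amplitude` their
#' peak intensity, and `noise_sigma` the SD of additive electronic noise.
#'
#' `pc_texture_params()` and `cp_texture_params()` are the package's
#' default two-class study conditions: pancreatic cancer as a coarser
#' (correlation length 6 px), hypoechoic (echogenicity 90) texture with
#' few bright foci; chronic pancreatitis as a finer (2 px), somewhat
#' brighter (echogenicity 115) texture rich in hyperechoic foci.
#'
#' @param correlation_length Speckle grain size, pixels (> 0).
#' @param echogenicity Mean intensity in `[0, 255]`.
#' @param focus_rate Expected bright foci per 1,000 px^2 (>= 0).
#' @param focus_amplitude Focus peak intensity, intensity units.
#' @param noise_sigma Additive Gaussian noise SD.
#' @return List of class `"eus_texture_params"`.
#' @export
texture_params <- function(correlation_length = 3, echogenicity = 100,
                           focus_rate = 0.5, focus_amplitude = 60,
                           noise_sigma = 8) {
  stopifnot(correlation_length > 0, echogenicity >= 0, echogenicity <= 255,
            focus_rate >= 0, focus_amplitude >= 0, noise_sigma >= 0)
  structure(list(correlation_length = correlation_length,
                 echogenicity = echogenicity, focus_rate = focus_rate,
                 focus_amplitude = focus_amplitude,
                 noise_sigma = noise_sigma),
            class = "eus_texture_params")
}

#' @rdname texture_params
#' @export
pc_texture_params <- function() {
  texture_params(correlation_length = 6, echogenicity = 90,
                 focus_rate = 0.2, focus_amplitude = 60, noise_sigma = 8)
}

#' @rdname texture_params
#' @export
cp_texture_params <- function() {
  texture_params(correlation_length = 2, echogenicity = 115,
                 focus_rate = 1.5, focus_amplitude = 80, noise_sigma = 8)
}

# Circular (torus) Gaussian blur via FFT; handles any kernel width.
gaussian_blur_fft <- function(mat, sigma) {
  h <- nrow(mat); w <- ncol(mat)
  gr <- stats::dnorm(pmin(0:(h - 1), h - (0:(h - 1))), sd = sigma)
  gc <- stats::dnorm(pmin(0:(w - 1), w - (0:(w - 1))), sd = sigma)
  k <- outer(gr, gc)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(mat) * stats::fft(k), inverse = TRUE)) / (h * w)
}

#' Generate one speckled grayscale texture
#'
#' Magnitude of a complex Gaussian white-noise field smoothed with a
#' Gaussian kernel of width `correlation_length` (Rayleigh-like speckle),
#' rescaled so its mean equals `echogenicity`, plus Poisson-placed
#' Gaussian bright blobs at `focus_rate` foci per 1,000 px^2, plus
#' additive Gaussian noise, clipped to `[0, 255]` and rounded. Fully
#' determined by `seed`.
#'
#' @param params A [texture_params()].
#' @param size `c(height, width)`, at least 16x16.
#' @param seed Integer seed.
#' @return Integer grey-level matrix.
#' @export
generate_texture <- function(params, size = c(64, 64), seed = 1L) {
  h <- size[1]; w <- size[2]
  if (h < 16 || w < 16) abort("size must be at least 16x16")
  withr::with_seed(as.integer(seed), {
    re <- gaussian_blur_fft(matrix(rnorm(h * w), h, w), params$correlation_length)
    im <- gaussian_blur_fft(matrix(rnorm(h * w), h, w), params$correlation_length)
    mag <- sqrt(re^2 + im^2)
    img <- mag / mean(mag) * params$echogenicity
    n_foci <- rpois(1, params$focus_rate * h * w / 1000)
    if (n_foci > 0) {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (i in seq_len(n_foci)) {
        fr <- stats::runif(1, 1, h); fc <- stats::runif(1, 1, w)
        img <- img + params$focus_amplitude *
          exp(-((rows - fr)^2 + (cols - fc)^2) / (2 * 1.5^2))
      }
    }
    if (params$noise_sigma > 0)
      img <- img + matrix(rnorm(h * w, sd = params$noise_sigma), h, w)
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    img
  })
}

# Per-image seed derived from the master seed by a fixed LCG-style hash,
# kept below 2^31 so cohorts are reproducible across platforms.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 69069 + as.numeric(index) * 12345) %%
               2147483629)
}

#' Generate a labelled two-class texture cohort
#'
#' Draws `n_pc` textures from the PC parameters and `n_cp` from the CP
#' parameters, each with its own seed derived deterministically from the
#' master seed, labelled PC = 1 / CP = 0.
#'
#' @param params_pc,params_cp [texture_params()] for the two classes.
#' @param n_pc,n_cp Class sizes (>= 2 each).
#' @param size Image size `c(height, width)`.
#' @param seed Master seed.
#' @return Tibble with columns `case_id`, `label`, `image` (list of
#'   matrices), `seed`.
#' @export
generate_cohort <- function(params_pc = pc_texture_params(),
                            params_cp = cp_texture_params(),
                            n_pc = 60L, n_cp = 60L,
                            size = c(64, 64), seed = 1L) {
  if (n_pc < 2 || n_cp < 2) abort("each class needs at least 2 cases")
  n <- n_pc + n_cp
  label <- c(rep(1L, n_pc), rep(0L, n_cp))
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  images <- purrr::map(seq_len(n), function(i) {
    p <- if (label[i] == 1L) params_pc else params_cp
    generate_texture(p, size = size, seed = seeds[i])
  })
  tibble(case_id = sprintf("case_%04d", seq_len(n)),
         label = label, image = images, seed = seeds)
}
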