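# Texture feature bank: 15 first-order statistic images, 21 co-occurrence
# feature images and 24 Gabor response images (12 filters x real/imaginary),
# computed per pixel on each of the hue, saturation and intensity channels
# and aggregated by mean, population standard deviation and histogram mode:
# 3 x (15 + 21 + 24) x 3 = 540 features.

#' Convert RGB to hue / saturation / intensity planes
#'
#' Hue and saturation follow the standard hexcone (HSV) model; intensity is
#' `(R + G + B) / 3`. Each plane is linearly rescaled to `[0, 255]` and
#' rounded to integers (as required for co-occurrence accumulation).
#'
#' @param image h x w x 3 RGB array with values in 0-255.
#' @return List of integer matrices `hue`, `saturation`, `intensity`.
#' @export
to_hsi <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stopf("image must be an h x w x 3 array")
  rgbm <- rbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
                as.numeric(image[, , 3]))
  hsv <- rgb2hsv(rgbm, maxColorValue = 255)
  shape <- function(v) matrix(as.integer(round(pmin(pmax(v, 0), 255))), d[1], d[2])
  list(hue = shape(hsv[1, ] * 255),
       saturation = shape(hsv[2, ] * 255),
       intensity = shape((image[, , 1] + image[, , 2] + image[, , 3]) / 3))
}

# ---- first-order statistics ------------------------------------------------

sobel_kernels <- function() {
  v <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)  # d/drow
  h <- t(v)                                                          # d/dcol
  d1 <- matrix(c(0, 1, 2, -1, 0, 1, -2, -1, 0), 3, 3, byrow = TRUE)
  d2 <- matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3, 3, byrow = TRUE)
  list(vertical = v, horizontal = h, diag1 = d1, diag2 = d2)
}

# Classic compass kernels; the N, NE and E responses are used.
kirsch_kernels <- function() {
  list(N = matrix(c(-3, -3, 5, -3, 0, 5, -3, -3, 5), 3, 3),
       NE = matrix(c(-3, 5, 5, -3, 0, 5, -3, -3, -3), 3, 3),
       E = matrix(c(5, 5, 5, -3, 0, -3, -3, -3, -3), 3, 3))
}

#' First-order statistic feature images
#'
#' 15 per-pixel feature images with reflected boundary handling: sliding
#' window mean, median, (population) standard deviation and range; Sobel
#' responses along the vertical, horizontal and both diagonal axes; Kirsch
#' compass responses (N, NE, E); central-difference gradients along the
#' vertical and horizontal axes; their difference; and the diagonal
#' derivative.
#'
#' @param plane Single-channel numeric matrix.
#' @param window Odd sliding-window size (default 3).
#' @return Named list of 15 matrices.
#' @export
first_order_images <- function(plane, window = 3) {
  if (!is_odd_window(window)) stopf("window must be an odd integer >= 3")
  if (window > min(dim(plane))) stopf("window larger than image")
  k <- window %/% 2L
  box <- matrix(1 / window^2, window, window)
  mu <- filter_reflect(plane, box)
  mu2 <- filter_reflect(plane^2, box)
  med <- sliding_median_cpp(pad_reflect(plane * 1.0, k), k)
  sk <- sobel_kernels()
  kk <- kirsch_kernels()
  gv <- filter_reflect(plane, matrix(c(-0.5, 0, 0.5), 3, 1))   # d/drow
  gh <- filter_reflect(plane, matrix(c(-0.5, 0, 0.5), 1, 3))   # d/dcol
  diag_k <- matrix(0, 3, 3); diag_k[1, 1] <- -0.5; diag_k[3, 3] <- 0.5
  list(mean = mu,
       median = med,
       std = sqrt(pmax(mu2 - mu^2, 0)),
       range = local_extreme(plane, k, pmax) - local_extreme(plane, k, pmin),
       sobel_v = filter_reflect(plane, sk$vertical),
       sobel_h = filter_reflect(plane, sk$horizontal),
       sobel_d1 = filter_reflect(plane, sk$diag1),
       sobel_d2 = filter_reflect(plane, sk$diag2),
       kirsch_n = filter_reflect(plane, kk$N),
       kirsch_ne = filter_reflect(plane, kk$NE),
       kirsch_e = filter_reflect(plane, kk$E),
       grad_v = gv,
       grad_h = gh,
       grad_diff = gh - gv,
       diag_deriv = filter_reflect(plane, diag_k))
}

# ---- co-occurrence ---------------------------------------------------------

glcm_feature_names <- function() {
  c("autocorrelation", "contrast", "correlation", "cluster_prominence",
    "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
    "max_probability", "variance", "sum_average", "sum_variance",
    "sum_entropy", "difference_variance", "difference_entropy",
    "imc1", "imc2", "inverse_difference", "inverse_difference_norm",
    "inverse_difference_moment_norm")
}

default_glcm_offsets <- function() {
  matrix(c(0L, 1L,   # 0 degrees
           -1L, 1L,  # 45 degrees
           -1L, 0L,  # 90 degrees
           -1L, -1L),# 135 degrees
         ncol = 2, byrow = TRUE)
}

#' Co-occurrence (GLCM) feature images
#'
#' For each pixel, a symmetric, normalized 256-level co-occurrence matrix is
#' accumulated over all distance-1 pixel pairs inside the pixel's window
#' (default offsets: the four symmetric displacements at 0, 45, 90 and
#' 135 degrees), and 21 Haralick-family statistics are computed. The formula
#' sheet is documented in the package source (`src/glcm.cpp`).
#'
#' @param plane Integer matrix with values in 0-255.
#' @param window Odd window size (default 9).
#' @param offsets k x 2 integer matrix of (drow, dcol) displacements.
#' @return Named list of 21 matrices.
#' @export
cooccurrence_images <- function(plane, window = 9,
                                offsets = default_glcm_offsets()) {
  if (!is_odd_window(window)) stopf("window must be an odd integer >= 3")
  if (nrow(offsets) == 0L) stopf("offset set must be non-empty")
  p <- matrix(as.integer(plane), nrow(plane), ncol(plane))
  if (min(p) < 0L || max(p) > 255L) stopf("plane values must lie in [0, 255]")
  arr <- glcm_feature_planes_cpp(p, as.integer(window),
                                 matrix(as.integer(offsets), ncol = 2))
  setNames(lapply(seq_len(21), function(i) arr[, , i]), glcm_feature_names())
}

# ---- Gabor -----------------------------------------------------------------

#' Construct a Gabor filter bank
#'
#' Each filter is a Gaussian envelope modulated by a sinusoid:
#' `G(x, y) = exp(-((x'/sx)^2 + (y'/sy)^2) / 2) * cos(2 pi k x' / Wk)`
#' with `x' = x cos(t) + y sin(t)` and `y' = y cos(t) + x sin(t)`
#' (the printed axis transform; set `proper_rotation = TRUE` for the
#' conventional `y' = y cos(t) - x sin(t)`). The frequency shift `k` is in
#' cycles across the kernel width `Wk`. The default bank crosses
#' `kappa in {5, 9}` with six orientations `theta = e * pi / 6`,
#' `e in 0..5` — 12 filters, each with a real and an imaginary response.
#'
#' @param kappas Frequency shifts.
#' @param thetas Orientations in radians, in `[0, pi)`.
#' @param half_width Kernel half-width in pixels (kernel is
#'   `(2 half_width + 1)` square).
#' @param sigma_x,sigma_y Gaussian stds along the rotated axes (default
#'   `half_width / 2`).
#' @param proper_rotation Use the conventional rotation for `y'`.
#' @return List of filters; each has `real` and `imag` kernel matrices
#'   (kernels laid out in (row, col) space; `x` is the column offset and `y`
#'   the row offset) plus its parameters. Real kernels are adjusted to zero
#'   mean.
#' @export
gabor_bank <- function(kappas = c(5, 9), thetas = (0:5) * pi / 6,
                       half_width = 8, sigma_x = half_width / 2,
                       sigma_y = half_width / 2, proper_rotation = FALSE) {
  if (sigma_x <= 0 || sigma_y <= 0) stopf("sigma must be positive")
  wk <- 2 * half_width + 1
  off <- -half_width:half_width
  x <- matrix(rep(off, each = wk), wk, wk)   # column offset
  y <- matrix(rep(off, times = wk), wk, wk)  # row offset
  bank <- list()
  for (kp in kappas) for (th in thetas) {
    xp <- x * cos(th) + y * sin(th)
    yp <- if (proper_rotation) y * cos(th) - x * sin(th)
          else y * cos(th) + x * sin(th)
    env <- exp(-0.5 * ((xp / sigma_x)^2 + (yp / sigma_y)^2))
    re <- env * cos(2 * pi * kp * xp / wk)
    im <- env * sin(2 * pi * kp * xp / wk)
    re <- re - mean(re)
    bank[[length(bank) + 1L]] <- list(kappa = kp, theta = th,
                                      real = re, imag = im)
  }
  bank
}

#' Gabor filter response images
#'
#' Convolves the plane with every filter in the bank (reflected boundaries)
#' and returns the real and imaginary response per filter: 24 planes for the
#' default 12-filter bank.
#'
#' @param plane Single-channel numeric matrix.
#' @param bank A [gabor_bank()].
#' @return Named list of `2 * length(bank)` matrices
#'   (`gabor_k<kappa>_t<index>_{re,im}`).
#' @export
gabor_images <- function(plane, bank = gabor_bank()) {
  if (length(bank) == 0L) stopf("filter bank must be non-empty")
  out <- list()
  for (f in bank) {
    ti <- round(f$theta / (pi / 6))
    nm <- sprintf("gabor_k%g_t%d", f$kappa, ti)
    out[[paste0(nm, "_re")]] <- filter_reflect(plane, f$real)
    out[[paste0(nm, "_im")]] <- filter_reflect(plane, f$imag)
  }
  out
}

# ---- aggregation and assembly ----------------------------------------------

#' Aggregate a feature image to (mean, std, mode)
#'
#' Mean and population standard deviation over all pixels; the mode is the
#' center of the most populated of 256 equal-width bins spanning
#' `[min, max]` (ties resolved to the lowest bin; a constant plane returns
#' its value).
#'
#' @param plane Non-empty numeric matrix.
#' @return Named numeric vector `c(mean, std, mode)`.
#' @export
aggregate_plane <- function(plane) {
  v <- as.numeric(plane)
  if (length(v) == 0L) stopf("empty plane")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  rng <- range(v)
  mode <- if (rng[1] == rng[2]) rng[1] else {
    width <- diff(rng) / 256
    bins <- pmin(floor((v - rng[1]) / width), 255)
    counts <- tabulate(bins + 1L, nbins = 256L)
    b <- which.max(counts) - 1L          # which.max takes the lowest tie
    rng[1] + (b + 0.5) * width
  }
  c(mean = m, std = s, mode = mode)
}

texture_channels <- c("hue", "saturation", "intensity")

#' The 540-feature texture vector
#'
#' For each of the hue, saturation and intensity channels: 15 first-order,
#' 21 co-occurrence and 24 Gabor feature images, each aggregated by
#' (mean, std, mode). Features are ordered family-major: all first-order
#' features (135), then co-occurrence (189), then Gabor (216).
#'
#' @param image h x w x 3 RGB array (0-255).
#' @param fo_window First-order sliding-window size.
#' @param glcm_window Co-occurrence window size.
#' @param bank Gabor filter bank.
#' @return Named numeric vector of length 540.
#' @export
texture_vector <- function(image, fo_window = 3, glcm_window = 9,
                           bank = gabor_bank()) {
  channels <- to_hsi(image)
  agg_block <- function(maker) {
    unlist(lapply(texture_channels, function(ch) {
      planes <- maker(channels[[ch]])
      unlist(lapply(names(planes), function(nm) {
        s <- aggregate_plane(planes[[nm]])
        setNames(s, paste(ch, nm, names(s), sep = "_"))
      }))
    }))
  }
  fo <- agg_block(function(p) first_order_images(p, fo_window))
  co <- agg_block(function(p) cooccurrence_images(p, glcm_window))
  gb <- agg_block(function(p) gabor_images(p, bank))
  stopifnot(length(fo) == 135L, length(co) == 189L, length(gb) == 216L)
  out <- c(fo, co, gb)
  stopifnot(length(out) == 540L)
  out
}

#' Names of the 540 texture features, in order
#' @param bank Gabor bank used (names depend on its parameters).
#' @return Character vector of length 540.
#' @export
texture_feature_names <- function(bank = gabor_bank()) {
  fo_names <- c("mean", "median", "std", "range", "sobel_v", "sobel_h",
                "sobel_d1", "sobel_d2", "kirsch_n", "kirsch_ne", "kirsch_e",
                "grad_v", "grad_h", "grad_diff", "diag_deriv")
  gb_names <- unlist(lapply(bank, function(f) {
    ti <- round(f$theta / (pi / 6))
    sprintf("gabor_k%g_t%d_%s", f$kappa, ti, c("re", "im"))
  }))
  stats3 <- c("mean", "std", "mode")
  block <- function(plane_names)
    unlist(lapply(texture_channels, function(ch)
      unlist(lapply(plane_names, function(nm) paste(ch, nm, stats3, sep = "_")))))
  c(block(fo_names), block(glcm_feature_names()), block(gb_names))
}
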