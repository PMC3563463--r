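test_that("HSI conversion: gray has zero saturation, red a constant hue", {
  gray <- array(128, dim = c(4, 4, 3))
  ch <- to_hsi(gray)
  expect_true(all(ch$saturation == 0))
  expect_true(all(ch$intensity == 128))
  red <- array(0, dim = c(4, 4, 3)); red[, , 1] <- 200
  chr <- to_hsi(red)
  expect_equal(length(unique(as.numeric(chr$hue))), 1L)
  expect_true(all(chr$saturation == 255))
  expect_equal(dim(chr$hue), c(4, 4))
})

test_that("first-order images: 15 planes with the expected degenerate values", {
  const <- matrix(7, 16, 16)
  fo <- first_order_images(const)
  expect_length(fo, 15L)
  expect_true(all(vapply(fo, function(p) all(dim(p) == c(16, 16)), TRUE)))
  for (nm in c("std", "range", "sobel_v", "sobel_h", "sobel_d1", "sobel_d2",
               "grad_v", "grad_h", "grad_diff", "diag_deriv"))
    expect_equal(max(abs(fo[[nm]])), 0, info = nm)
  expect_equal(fo$mean, const)
  expect_equal(fo$median, const)
  # horizontal ramp of slope 1: horizontal gradient 1, vertical 0 (interior)
  ramp <- matrix(rep(1:16, each = 16), 16, 16, byrow = TRUE)
  ramp <- t(ramp)  # value = column index
  fo2 <- first_order_images(ramp)
  expect_equal(fo2$grad_h[5:12, 5:12], matrix(1, 8, 8))
  expect_equal(fo2$grad_v[5:12, 5:12], matrix(0, 8, 8))
  expect_error(first_order_images(const, window = 4), "odd")
  expect_error(first_order_images(matrix(1, 2, 2), window = 3), "larger")
})

test_that("co-occurrence planes: degenerate windows and the checkerboard", {
  const <- matrix(100L, 12, 12)
  co <- cooccurrence_images(const, window = 5)
  expect_length(co, 21L)
  expect_equal(co$energy[6, 6], 1)
  expect_equal(co$entropy[6, 6], 0)
  expect_equal(co$contrast[6, 6], 0)
  expect_equal(co$max_probability[6, 6], 1)
  # 1-px checkerboard of {0,255}, horizontal distance-1 offset: all pairs differ
  cb <- matrix(0L, 12, 12); cb[(row(cb) + col(cb)) %% 2 == 0] <- 255L
  coh <- cooccurrence_images(cb, window = 5, offsets = matrix(c(0L, 1L), 1))
  expect_equal(coh$contrast[6, 6], 255^2)
  expect_equal(coh$dissimilarity[6, 6], 255)
  expect_error(cooccurrence_images(const, offsets = matrix(integer(0), 0, 2)),
               "non-empty")
})

test_that("co-occurrence features match the dense reference implementation", {
  set.seed(5)
  plane <- matrix(sample(0:7, 15 * 15, replace = TRUE), 15, 15)
  co <- cooccurrence_images(plane, window = 7)
  for (px in list(c(8, 8), c(2, 3), c(15, 15))) {
    ref <- ref_glcm_pixel(plane, px[1], px[2], 7, histocascade:::default_glcm_offsets())
    got <- vapply(co, function(m) m[px[1], px[2]], 0)
    expect_equal(unname(got), unname(ref), tolerance = 1e-10)
  }
})

test_that("per-pixel GLCMs are normalized and symmetric by construction", {
  # energy of a distribution equals 1 only when one entry holds all mass;
  # entropy 0 likewise; together with the reference check above these pin
  # the normalization. Here: sum of probabilities via the reference builder.
  set.seed(9)
  plane <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  ref <- ref_glcm_pixel(plane, 5, 5, 9, histocascade:::default_glcm_offsets())
  expect_true(all(is.finite(ref)))
  co <- cooccurrence_images(plane, window = 9)
  expect_equal(co$entropy[5, 5], ref[["entropy"]], tolerance = 1e-10)
})

test_that("Gabor bank: 12 filters, unit center response before adjustment", {
  bank <- gabor_bank()
  expect_length(bank, 12L)
  expect_equal(sort(unique(vapply(bank, `[[`, 0, "kappa"))), c(5, 9))
  expect_equal(sort(unique(vapply(bank, `[[`, 0, "theta"))), (0:5) * pi / 6)
  f <- bank[[1]]  # kappa 5, theta 0
  ctr <- 9  # half_width 8 -> center index
  # rebuild the unadjusted kernel from the formula: center value is
  # exp(0) * cos(0) = 1; the stored real kernel subtracts its mean
  off <- -8:8
  x <- matrix(rep(off, each = 17), 17, 17)
  y <- matrix(rep(off, times = 17), 17, 17)
  raw <- exp(-0.5 * ((x / 4)^2 + (y / 4)^2)) * cos(2 * pi * 5 * x / 17)
  expect_equal(raw[ctr, ctr], 1)
  expect_equal(f$real, raw - mean(raw), tolerance = 1e-12)
  expect_equal(mean(f$real), 0, tolerance = 1e-12)
  expect_equal(f$imag[ctr, ctr], 0)
  expect_error(gabor_bank(sigma_x = 0), "sigma")
})

test_that("Gabor responses prefer gratings at the matched orientation", {
  bank <- gabor_bank()
  wk <- 17
  colidx <- matrix(rep(1:64, each = 64), 64, 64)   # value = column index
  rowidx <- t(colidx)                              # value = row index
  grat_cols <- cos(2 * pi * 5 * colidx / wk) * 50 + 128  # matches theta = 0
  grat_rows <- cos(2 * pi * 5 * rowidx / wk) * 50 + 128  # orthogonal
  gi <- gabor_images(grat_cols, bank)
  expect_length(gi, 24L)
  matched <- mean(abs(gi[["gabor_k5_t0_re"]][20:44, 20:44]))
  mismatched <- mean(abs(gabor_images(grat_rows, bank)[["gabor_k5_t0_re"]][20:44, 20:44]))
  expect_gt(matched, mismatched)
})

test_that("rotating a grating by 90 degrees moves the peak orientation", {
  bank <- gabor_bank()
  wk <- 17
  colidx <- matrix(rep(1:64, each = 64), 64, 64)
  grat <- cos(2 * pi * 5 * colidx / wk) * 50 + 128
  energy_by_theta <- function(img) {
    resp <- gabor_images(img, bank)
    vapply(0:5, function(ti)
      mean(abs(resp[[sprintf("gabor_k5_t%d_re", ti)]][20:44, 20:44])), 0)
  }
  e0 <- energy_by_theta(grat)
  e90 <- energy_by_theta(t(grat)[, 64:1])  # 90-degree rotation
  expect_equal(which.max(e0), 1L)   # theta = 0 dominates
  expect_equal(which.max(e90), 4L)  # theta = pi/2 dominates after rotation
})

test_that("plane aggregation: mean/std/mode with the documented tie rule", {
  const <- matrix(3.5, 5, 5)
  expect_equal(unname(aggregate_plane(const)), c(3.5, 0, 3.5))
  # half 0s, half 10s, one 5: tie between the extreme bins resolves low
  v <- matrix(c(rep(0, 12), 5, rep(10, 12)), 5, 5)
  agg <- aggregate_plane(v)
  expect_equal(unname(agg[["mode"]]), 0, tolerance = 0.03)
  set.seed(11)
  z <- matrix(rnorm(1e6), 1000, 1000)
  aggz <- aggregate_plane(z)
  expect_equal(unname(aggz[["mean"]]), 0, tolerance = 0.01)
  expect_equal(unname(aggz[["std"]]), 1, tolerance = 0.01)
})

test_that("the texture vector has the documented block structure", {
  roi <- quick_roi("BE", seed = 8)
  tv <- texture_vector(roi$image)
  expect_length(tv, 540L)
  expect_identical(names(tv), texture_feature_names())
  nm <- names(tv)
  fo_block <- nm[1:135]; co_block <- nm[136:324]; gb_block <- nm[325:540]
  expect_true(all(grepl("mean|median|std|range|sobel|kirsch|grad|diag", fo_block)))
  expect_true(all(grepl("gabor", gb_block)))
  expect_false(any(grepl("gabor", co_block)))
  # determinism: identical image, identical vector
  expect_identical(texture_vector(roi$image), tv)
})
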