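test_that("phase correlation recovers integer cyclic shifts", {
  im <- smooth_texture(96, seed = 2)
  shifted <- im[c(90:96, 1:89), c(4:96, 1:3)]   # content moved +7 rows, -3 cols
  pc <- phase_correlate(im, shifted)
  expect_equal(as.numeric(pc$shift), c(-3, 7), tolerance = 0.1)
  expect_equal(round(as.numeric(pc$shift)), c(-3, 7))
  # band-limited content populates only part of the spectrum, which caps
  # the phase-peak height; it must still stand clearly above noise level
  expect_gt(pc$confidence, 0.15)
  same <- phase_correlate(im, im)
  expect_equal(as.numeric(same$shift), c(0, 0), tolerance = 1e-6)
  expect_gt(same$confidence, 0.3)
  white <- with_test_seed(3, matrix(runif(96 * 96), 96, 96))
  expect_equal(phase_correlate(white, white)$confidence, 1, tolerance = 1e-6)
})

test_that("sub-pixel shifts are recovered within a quarter pixel", {
  n <- 128
  for (true_dx in c(2.3, -4.6)) {
    a <- smooth_texture(n, seed = 5)
    # shift via Fourier phase ramp (exact periodic translation)
    ph <- exp(-2i * pi * stagescan:::fft_freq(n) * true_dx)
    b <- Re(stats::fft(stats::fft(a) * matrix(ph, n, n, byrow = TRUE),
                       inverse = TRUE)) / n^2
    pc <- phase_correlate(a, b)
    expect_equal(pc$shift[["dx"]], true_dx, tolerance = 0.25)
    expect_lt(abs(pc$shift[["dy"]]), 0.25)
  }
})

test_that("pairwise offsets recover constructed tile cuts", {
  scene <- smooth_texture(280, seed = 8)
  A <- scene[41:168, 31:158]
  B <- scene[48:175, 127:254]   # offset (dx, dy) = (96, 7)
  est <- pairwise_offset(A, B, c(96, 0), search_radius_px = 12)
  expect_equal(est$dx, 96, tolerance = 0.3)
  expect_equal(est$dy, 7, tolerance = 0.3)
  expect_false(est$fallback)
})

test_that("registration is translation-equivariant", {
  scene <- smooth_texture(260, seed = 4)
  A1 <- scene[1:128, 1:128];  B1 <- scene[1:128, 97:224]
  A2 <- scene[21:148, 11:138]; B2 <- scene[21:148, 107:234]
  e1 <- pairwise_offset(A1, B1, c(96, 0))
  e2 <- pairwise_offset(A2, B2, c(96, 0))
  expect_equal(e1$dx, e2$dx, tolerance = 0.3)
  expect_equal(e1$dy, e2$dy, tolerance = 0.3)
})

test_that("featureless or random overlaps fall back to the nominal offset", {
  a <- with_test_seed(1, matrix(runif(128 * 128), 128, 128))
  b <- with_test_seed(2, matrix(runif(128 * 128), 128, 128))
  est <- pairwise_offset(a, b, c(96, 0), search_radius_px = 10)
  expect_true(est$fallback)
  expect_equal(c(est$dx, est$dy), c(96, 0))
  expect_lt(est$confidence, 0.15)
})

test_that("too-narrow predicted overlaps are rejected", {
  a <- smooth_texture(64, seed = 1)
  expect_error(pairwise_offset(a, a, c(50, 0)), "32 px")
})

test_that("displacement measurement converts pixel shifts to µm", {
  im <- smooth_texture(128, seed = 6)
  expect_equal(as.numeric(measure_displacement(im, im, 0.386)), c(0, 0))
  sh13 <- im[, c(116:128, 1:115)]   # content moved +13 columns
  d <- measure_displacement(im, sh13, 0.386)
  expect_equal(abs(d[["dx_um"]]), 13 * 0.386, tolerance = 0.05)
  expect_equal(13 * 0.386, 5.018)
  # the stability bound: 7 px at 0.386 µm/px is below 3 µm
  sh7 <- im[, c(122:128, 1:121)]
  d7 <- measure_displacement(im, sh7, 0.386)
  expect_equal(abs(d7[["dx_um"]]), 2.702, tolerance = 0.05)
  expect_lt(abs(d7[["dx_um"]]), 3)
})

test_that("drift tracking reports per-frame displacement against frame one", {
  im <- smooth_texture(96, seed = 9)
  static <- replicate(5, im, simplify = FALSE)
  dt <- drift_track(static, pixel_um = 1)
  expect_equal(unname(attr(dt, "max_drift_um")), c(0, 0), tolerance = 1e-6)

  # linear drift of 0.5 px/frame over 10 frames -> max 4.5 px
  n <- 96
  frames <- lapply(0:9, function(k) {
    ph <- exp(-2i * pi * stagescan:::fft_freq(n) * 0.5 * k)
    Re(stats::fft(stats::fft(im) * matrix(ph, n, n, byrow = TRUE),
                  inverse = TRUE)) / n^2
  })
  dt2 <- drift_track(frames, pixel_um = 1)
  expect_equal(max(abs(dt2$dx_um)), 4.5, tolerance = 0.15)
  expect_lt(max(abs(dt2$dy_um)), 0.2)
  expect_error(drift_track(list(im), 1), "at least 2")
})
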