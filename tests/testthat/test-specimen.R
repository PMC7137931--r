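test_that("specimen volumes enforce their invariants", {
  expect_error(specimen_volume(matrix(1, 2, 2), 1, 1), "3D")
  arr <- array(1, c(3, 3, 2))
  expect_error(specimen_volume(arr, -1, 1), "positive")
  bad <- arr; bad[1] <- -5
  expect_error(specimen_volume(bad, 1, 1), ">= 0")
  v <- specimen_volume(arr, 0.5, 2, origin = c(10, 20, 30))
  ext <- specimen_extent(v)
  expect_equal(ext$x, c(10, 11))
  expect_equal(ext$z, c(30, 32))
})

test_that("nerve-net generator is deterministic and rejects bad extents", {
  expect_error(make_nervenet_specimen(c(-10, 50, 10), 5, seed = 1), "positive")
  a <- make_nervenet_specimen(c(80, 80, 20), 5, seed = 3)
  b <- make_nervenet_specimen(c(80, 80, 20), 5, seed = 3)
  expect_identical(a$intensity, b$intensity)
  c2 <- make_nervenet_specimen(c(80, 80, 20), 5, seed = 4)
  expect_false(identical(a$intensity, c2$intensity))
})

test_that("zero-amplitude nerve net degenerates to pure background", {
  v <- make_nervenet_specimen(c(100, 100, 20), 1, seed = 1, amplitude = 0,
                              background = 0.05)
  expect_equal(max(v$intensity), 0.05)
  expect_equal(min(v$intensity), 0.05)
})

test_that("bright voxels of a generated nerve net are sparse but present", {
  v <- make_nervenet_specimen(c(500, 500, 50), 40, seed = 7)
  frac <- mean(v$intensity > 0.1)   # threshold well above the 0.05 background
  expect_gt(frac, 0)
  expect_lt(frac, 0.20)
})

test_that("filaments lie on a smooth height surface (depth varies across XY)", {
  v <- make_nervenet_specimen(c(300, 300, 40), 30, seed = 2)
  bright <- which(v$intensity > 0.5, arr.ind = TRUE)
  expect_gt(nrow(bright), 100)
  # bright structure spans several depths overall, but any local
  # neighbourhood is confined to a narrow band
  expect_gt(diff(range(bright[, 3])), 2)
  sub <- bright[bright[, 1] < 50 & bright[, 2] < 50, , drop = FALSE]
  if (nrow(sub) > 10) expect_lt(diff(range(sub[, 3])), 6)
})

test_that("USAF target geometry follows the chart formulas", {
  tgt <- make_usaf_target(7, pixel_um = 0.386)
  g76 <- tgt$geometry[tgt$geometry$group == 7 & tgt$geometry$element == 6, ][1, ]
  # period = (1000 / res_lp) / pixel size
  expect_equal(g76$period_px, (1000 / res_lp(7, 6)) / 0.386, tolerance = 1e-10)
  expect_equal(g76$period_px, 11.36, tolerance = 1e-2)
  # pattern is binary at full contrast before any blur
  expect_setequal(unique(as.vector(tgt$image)), c(0, 1))
  # bars are dark on bright: the element bounding box contains both levels
  box <- tgt$image[g76$row0:g76$row1, g76$col0:g76$col1]
  expect_true(any(box == 0) && any(box == 1))
})

test_that("coarse USAF elements have metre-scale periods", {
  tgt <- make_usaf_target(0, pixel_um = 40)
  g01 <- tgt$geometry[tgt$geometry$group == 0 & tgt$geometry$element == 1, ][1, ]
  expect_equal(g01$res_lp_mm, 1)
  expect_equal(g01$period_um, 1000)
})

test_that("undersampled USAF request errors and names the finest resolvable element", {
  # at 2 µm/px group 7 bars span < 2 px; group 6 is still resolvable
  err <- tryCatch(make_usaf_target(7, pixel_um = 2, min_group = 6),
                  error = conditionMessage)
  expect_match(err, "finest resolvable element is group 6")
  # nothing resolvable at all is reported as such
  expect_error(make_usaf_target(7, pixel_um = 5),
               "undersamples every requested element")
})

test_that("slanted-edge images carry the requested geometry", {
  im <- make_slant_edge(100, 5, low = 0, high = 1)
  expect_equal(dim(im), c(100, 100))
  expect_lt(max(abs(range(im) - c(0, 1))), 1e-9)
  # bright side at larger X
  expect_gt(mean(im[, 90]), mean(im[, 10]))
  # each row's transition column advances with the 5 degree slope
  mid <- function(r) which.min(abs(im[r, ] - 0.5))
  expect_equal(mid(90) - mid(10), 80 * tan(5 * pi / 180), tolerance = 0.3)
})
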