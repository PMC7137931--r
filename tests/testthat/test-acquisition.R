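test_that("focus score is zero for constant images and offset-invariant", {
  expect_equal(focus_score(matrix(7, 32, 32)), 0)
  im <- smooth_texture(48, seed = 3)
  expect_gt(focus_score(im), 0)
  expect_equal(focus_score(im), focus_score(im + 100))
  expect_error(focus_score(matrix(numeric(0), 0, 0)), "empty")
})

test_that("sharper renders score higher than defocused ones", {
  tgt <- make_usaf_target(6, pixel_um = 0.8)
  n <- min(dim(tgt$image), 120)
  arr <- array(0.02, c(nrow(tgt$image), ncol(tgt$image), 3))
  arr[, , 2] <- tgt$image
  vol <- specimen_volume(arr, pitch_xy = 0.8, pitch_z = 5)
  opt <- clean_optics(fov_px = 96, pixel_um = 0.8)
  sharp <- focus_score(render_frame(vol, c(5, 5, 5), opt))
  soft <- focus_score(render_frame(vol, c(5, 5, 10), opt))   # 5 µm defocus
  expect_gt(sharp, soft)
})

test_that("maximum intensity projection is the per-pixel maximum", {
  # oracle: brute-force max over randomly generated stacks
  for (s in 1:3) {
    stack <- with_test_seed(s, lapply(1:5, function(i) matrix(runif(64), 8, 8)))
    mip <- max_intensity_projection(stack)
    oracle <- stack[[1]]
    for (p in stack[-1]) for (i in seq_along(oracle))
      oracle[i] <- max(oracle[i], p[i])
    expect_equal(mip, oracle)
    for (p in stack) expect_true(all(mip >= p))
  }
  one <- matrix(1:9, 3, 3)
  expect_identical(max_intensity_projection(list(one)), one)
  expect_error(max_intensity_projection(list(one, matrix(0, 2, 2))), "shape")
})

test_that("Z-correction recentres the best-focus plane", {
  expect_equal(z_correct(list(focus_scores = c(1, 5, 1), best_index = 2),
                         dz_um = 2, nz = 3), 0)
  # best plane 16 of 20 (1-based; 15 with 0-based counting), dz 2 µm
  scores <- rep(0.1, 20); scores[16] <- 1
  expect_equal(z_correct(scores, dz_um = 2, nz = 20), 11)
  # featureless tile: zero offset plus a warning
  expect_warning(off <- z_correct(rep(0, 5), dz_um = 2, nz = 5), "featureless")
  expect_equal(off, 0)
  # ties break toward the lower plane index
  expect_equal(z_correct(c(1, 1), dz_um = 2, nz = 2), -1)
})

test_that("run_scan produces the planned tile and frame counts", {
  vol <- small_nervenet()
  opt <- optics_model(fov_px = 48)
  plan <- plan_serpentine(3, 2, 48 * opt$pixel_um, 0.25, 0.30,
                          origin = c(40, 40), nz = 4, dz_um = 2.5,
                          z_start = 60)
  res <- run_scan(plan, vol, opt, default_piezo_stage(c(x = 40, y = 40, z = 60)),
                  seed = 5)
  expect_equal(res$manifest$n_tiles_done, 6)
  expect_equal(res$manifest$n_frames, 24)   # nx * ny * nz
  expect_length(res$mips, 6)
  expect_length(res$tiles[[1]]$focus_scores, 4)
  expect_equal(res$tiles[[1]]$best_index,
               which.max(res$tiles[[1]]$focus_scores))
  expect_equal(res$tiles[[1]]$z_correction_um, 0)
})

test_that("a 1x1 scan acquires one tile without XY moves", {
  vol <- small_nervenet()
  opt <- optics_model(fov_px = 48)
  plan <- plan_serpentine(1, 1, 48 * opt$pixel_um, origin = c(60, 60),
                          nz = 3, dz_um = 2.5, z_start = 62)
  res <- run_scan(plan, vol, opt, default_piezo_stage(), seed = 2)
  expect_equal(res$manifest$n_tiles_done, 1)
  xy_moves <- subset(res$stage$log, axis %in% c("x", "y") & commanded_um != 0)
  expect_equal(nrow(xy_moves), 0)
})

test_that("re-running a scan with the same seed is fully reproducible", {
  vol <- small_nervenet()
  opt <- optics_model(fov_px = 48)
  plan <- plan_serpentine(2, 2, 48 * opt$pixel_um, 0.25, 0.30,
                          origin = c(50, 50), nz = 3, dz_um = 2.5,
                          z_start = 62)
  r1 <- run_scan(plan, vol, opt, default_piezo_stage(c(x = 50, y = 50, z = 62)),
                 seed = 11)
  r2 <- run_scan(plan, vol, opt, default_piezo_stage(c(x = 50, y = 50, z = 62)),
                 seed = 11)
  expect_identical(r1$mips, r2$mips)
  expect_identical(r1$tiles, r2$tiles)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
})

test_that("a mid-scan failure yields a resumable manifest with the failure marker", {
  vol <- small_nervenet()   # 200 x 200 µm volume
  opt <- optics_model(fov_px = 48)
  # second row walks off the specimen in Y -> render error mid-scan
  plan <- plan_serpentine(2, 2, 48 * opt$pixel_um, 0, 0,
                          origin = c(60, 170 + 50), nz = 2, dz_um = 2.5,
                          z_start = 62)
  plan$tiles$y_um <- c(170, 170, 900, 900)
  res <- run_scan(plan, vol, opt, default_piezo_stage(c(x = 60, y = 170, z = 62)),
                  seed = 3)
  expect_equal(res$manifest$n_tiles_done, 2)
  expect_match(res$manifest$failure, "tile 3")
})

test_that("scan output files land on disk with a manifest", {
  vol <- small_nervenet()
  opt <- optics_model(fov_px = 48)
  plan <- plan_serpentine(2, 1, 48 * opt$pixel_um, 0.25, 0.30,
                          origin = c(50, 50), nz = 2, dz_um = 2.5,
                          z_start = 62)
  out <- withr::local_tempdir()
  res <- run_scan(plan, vol, opt, default_piezo_stage(c(x = 50, y = 50, z = 62)),
                  seed = 1, out_dir = out, keep_stacks = TRUE)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_length(list.files(out, pattern = "_mip\\.tif$"), 2)
  stack <- read_image_tiff(file.path(out, res$tiles[[1]]$stack_file))
  expect_length(stack, 2)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$n_frames, 4)
})
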