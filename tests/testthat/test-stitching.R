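test_that("global positions reproduce exactly consistent offsets", {
  # 2x2 grid with known positions
  truth <- rbind(c(0, 0), c(100, 2), c(-3, 90), c(97, 93))
  edges <- list()
  for (pair in list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))) {
    d <- truth[pair[2], ] - truth[pair[1], ]
    edges[[length(edges) + 1]] <- list(a = pair[1], b = pair[2],
                                       dx = d[1], dy = d[2], confidence = 1)
  }
  pos <- global_positions(edges, 4)
  expect_equal(unname(pos), unname(truth), tolerance = 1e-8)
})

test_that("one corrupted edge among redundant edges is voted down", {
  truth <- cbind(x = rep(c(0, 100, 200), 3),
                 y = rep(c(0, 95, 190), each = 3))
  edges <- list()
  idx <- function(i, j) (j - 1) * 3 + i
  for (j in 1:3) for (i in 1:3) {
    if (i < 3) {
      d <- truth[idx(i + 1, j), ] - truth[idx(i, j), ]
      edges[[length(edges) + 1]] <- list(a = idx(i, j), b = idx(i + 1, j),
                                         dx = d[1], dy = d[2], confidence = 0.9)
    }
    if (j < 3) {
      d <- truth[idx(i, j + 1), ] - truth[idx(i, j), ]
      edges[[length(edges) + 1]] <- list(a = idx(i, j), b = idx(i, j + 1),
                                         dx = d[1], dy = d[2], confidence = 0.9)
    }
  }
  edges[[2]]$dx <- edges[[2]]$dx + 40   # corrupt one edge
  pos <- global_positions(edges, 9)
  err <- sqrt(rowSums((pos - sweep(truth, 2, truth[1, ]))^2))
  expect_lt(max(err), 1)
})

test_that("a single tile anchors at the origin and disconnection is reported", {
  expect_equal(unname(global_positions(list(), 1)), matrix(0, 1, 2))
  edges <- list(list(a = 1, b = 2, dx = 10, dy = 0, confidence = 1))
  expect_error(global_positions(edges, 4), "disconnected")
})

test_that("composing exact cuts reassembles the original image", {
  scene <- smooth_texture(200, seed = 12) + 2
  tiles <- list(scene[1:120, 1:120], scene[1:120, 81:200],
                scene[81:200, 1:120], scene[81:200, 81:200])
  pos <- rbind(c(0, 0), c(80, 0), c(0, 80), c(80, 80))
  comp <- compose(tiles, pos, blend_width_px = 16)
  expect_equal(dim(comp), c(200, 200))
  # grey-level tolerance: scene spans ~4 units over 16-bit-like range
  expect_lt(max(abs(comp - scene)), 4 / 65535)
})

test_that("zero blend width means last writer wins", {
  t1 <- matrix(1, 10, 10); t2 <- matrix(2, 10, 10)
  comp <- compose(list(t1, t2), rbind(c(0, 0), c(5, 0)), blend_width_px = 0)
  expect_equal(comp[1, 6], 2)   # overlap column taken from the later tile
  expect_equal(comp[1, 3], 1)
  single <- compose(list(t1), rbind(c(0, 0)), blend_width_px = 8)
  expect_equal(single, t1)
})

test_that("stitching a cut-up synthetic image recovers injected integer shifts exactly", {
  scene <- smooth_texture(260, seed = 20)
  A <- scene[1:128, 1:128]
  B <- scene[(1:128) + 5, (1:128) + 103]  # true offset (dx, dy) = (103, 5)
  est <- pairwise_offset(A, B, c(96, 0), search_radius_px = 12)
  expect_equal(round(est$dx), 103)
  expect_equal(round(est$dy), 5)
  expect_lt(abs(est$dx - 103), 0.15)
  expect_lt(abs(est$dy - 5), 0.15)
})

test_that("a simulated piezo scan stitches to sub-2-px RMS against ground truth", {
  vol <- make_nervenet_specimen(c(800, 650, 40), 500, seed = 11,
                                origin_um = c(0, 0, 50),
                                surface_amplitude_um = 5)
  opt <- optics_model(fov_px = 384)
  plan <- plan_serpentine(5, 4, 384 * opt$pixel_um, 0.25, 0.30,
                          origin = c(60, 60), nz = 10, dz_um = 2.5,
                          z_start = 63)
  stage <- default_piezo_stage(c(x = 60, y = 60, z = 63))
  res <- run_scan(plan, vol, opt, stage, seed = 42)
  st <- stitch_scan(res, plan, opt$pixel_um)
  ach <- t(vapply(res$tiles, function(t) c(t$x_um, t$y_um), numeric(2))) /
    opt$pixel_um
  ach <- sweep(ach, 2, ach[1, ])
  rec <- sweep(st$positions, 2, st$positions[1, ])
  # piezo per-move error reaches +/-20%, yet recovered positions track truth
  dev_nominal <- max(abs(ach - sweep(cbind(plan$tiles$x_um, plan$tiles$y_um) /
                                       opt$pixel_um, 2,
                                     c(plan$tiles$x_um[1], plan$tiles$y_um[1]) /
                                       opt$pixel_um)))
  expect_gt(dev_nominal, 10)   # the stage really was inconsistent
  expect_lt(sqrt(mean((rec - ach)^2)), 2)
})
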