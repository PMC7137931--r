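#' Specimen volume container
#'
#' A `specimen_volume` is the ground truth for all simulated imaging: a 3D
#' fluorescence-intensity field with physical voxel pitch. The array is
#' indexed `[row, col, plane]` where row maps to Y (row 1 = minimum Y),
#' col to X, and plane to Z (plane 1 = shallowest; larger stage Z focuses
#' deeper). Voxel `[r, c, p]` is centred at
#' `origin + ((c-1) * pitch_xy, (r-1) * pitch_xy, (p-1) * pitch_z)` in µm.
#'
#' @param intensity 3D numeric array of fluorescence intensities (>= 0,
#'   arbitrary units).
#' @param pitch_xy Voxel pitch in X and Y, µm.
#' @param pitch_z Voxel pitch in Z, µm.
#' @param origin Physical position (µm) of voxel `[1, 1, 1]`, as
#'   `c(x, y, z)`.
#' @return An object of class `specimen_volume`.
#' @export
specimen_volume <- function(intensity, pitch_xy, pitch_z, origin = c(0, 0, 0)) {
  intensity <- unclass(intensity)
  if (length(dim(intensity)) != 3)
    stop("`intensity` must be a 3D array")
  if (any(intensity < 0, na.rm = TRUE))
    stop("specimen intensities must be >= 0")
  if (!is.numeric(pitch_xy) || pitch_xy <= 0 || !is.numeric(pitch_z) || pitch_z <= 0)
    stop("voxel pitches must be positive")
  if (length(origin) != 3)
    stop("`origin` must be c(x, y, z) in µm")
  structure(
    list(intensity = intensity, pitch_xy = pitch_xy, pitch_z = pitch_z,
         origin = as.numeric(origin)),
    class = "specimen_volume")
}

#' @export
print.specimen_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<specimen_volume> %d x %d x %d voxels (%.1f x %.1f x %.1f µm), pitch %.2f/%.2f µm\n",
    d[2], d[1], d[3],
    (d[2] - 1) * x$pitch_xy, (d[1] - 1) * x$pitch_xy, (d[3] - 1) * x$pitch_z,
    x$pitch_xy, x$pitch_z))
  invisible(x)
}

#' Physical extent of a specimen volume
#'
#' @param vol A [specimen_volume()].
#' @return Named list with `x`, `y`, `z` ranges in µm (voxel centres).
#' @export
specimen_extent <- function(vol) {
  d <- dim(vol$intensity)
  list(x = vol$origin[1] + c(0, (d[2] - 1) * vol$pitch_xy),
       y = vol$origin[2] + c(0, (d[1] - 1) * vol$pitch_xy),
       z = vol$origin[3] + c(0, (d[3] - 1) * vol$pitch_z))
}

#' Generate a synthetic nerve-net specimen
#'
#' Emulates a whole-mount fluorescently labelled epithelial nerve net: a
#' polygonal mesh of thin bright filaments draped over a smoothly varying
#' height surface, so the in-focus plane drifts across XY and Z-stacking is
#' genuinely required. Filaments are line segments between random anchor
#' points, rasterized with a Gaussian cross-section at the local surface
#' height over a uniform background.
#'
#' @param extent_um Physical size `c(x, y, z)` of the volume, µm.
#' @param n_filaments Number of filament segments (>= 1).
#' @param seed Integer seed; the volume is voxel-identical for a fixed seed.
#' @param pitch_xy,pitch_z Voxel pitch, µm.
#' @param background Background fluorescence level (arbitrary units).
#' @param amplitude Peak filament intensity above background. `0` gives a
#'   background-only volume (useful as a degenerate control).
#' @param surface_amplitude_um Peak-to-centre amplitude of the height
#'   surface; defaults to 25% of the Z extent.
#' @param filament_radius_um Gaussian cross-section sigma of filaments, µm.
#' @param origin_um Physical stage position of voxel `[1, 1, 1]`,
#'   `c(x, y, z)` µm. Place the specimen well inside the stage travel so a
#'   Z-stack (and its corrections) never reaches a hard stop.
#' @return A [specimen_volume()].
#' @export
make_nervenet_specimen <- function(extent_um, n_filaments, seed,
                                   pitch_xy = 1, pitch_z = 2.5,
                                   background = 0.05, amplitude = 1,
                                   surface_amplitude_um = NULL,
                                   filament_radius_um = 1.5,
                                   origin_um = c(0, 0, 0)) {
  extent_um <- as.numeric(extent_um)
  if (length(extent_um) != 3 || any(!is.finite(extent_um)) || any(extent_um <= 0))
    stop("`extent_um` must be three positive extents c(x, y, z) in µm")
  if (n_filaments < 1) stop("`n_filaments` must be >= 1")
  nx <- max(2L, ceiling(extent_um[1] / pitch_xy) + 1L)
  ny <- max(2L, ceiling(extent_um[2] / pitch_xy) + 1L)
  nz <- max(2L, ceiling(extent_um[3] / pitch_z) + 1L)
  if (is.null(surface_amplitude_um)) surface_amplitude_um <- 0.25 * extent_um[3]

  vol <- with_seed(seed, {
    arr <- array(background, dim = c(ny, nx, nz))
    # smooth height surface: z-centre plus a few random long-wavelength waves
    z_mid <- extent_um[3] / 2
    xs <- (seq_len(nx) - 1) * pitch_xy
    ys <- (seq_len(ny) - 1) * pitch_xy
    n_waves <- 3L
    kx <- stats::runif(n_waves, 0.4, 1.3) * 2 * pi / extent_um[1]
    ky <- stats::runif(n_waves, 0.4, 1.3) * 2 * pi / extent_um[2]
    ph <- stats::runif(n_waves, 0, 2 * pi)
    amp_w <- surface_amplitude_um * c(0.6, 0.3, 0.1)
    surface_at <- function(x, y) {
      z <- z_mid
      for (w in seq_len(n_waves))
        z <- z + amp_w[w] * sin(kx[w] * x + ky[w] * y + ph[w])
      pmin(pmax(z, 0), extent_um[3])
    }
    if (amplitude > 0) {
      # anchor points and near-neighbour segments form the polygonal mesh
      n_nodes <- max(4L, ceiling(0.7 * n_filaments) + 3L)
      px <- stats::runif(n_nodes, 0, extent_um[1])
      py <- stats::runif(n_nodes, 0, extent_um[2])
      node_amp <- amplitude * stats::runif(n_nodes, 0.8, 1.4)
      node_r <- stats::runif(n_nodes, 1.5, 3.5)
      r_vox <- filament_radius_um
      half <- max(1L, ceiling(3 * r_vox / pitch_xy))
      half_z <- max(1L, ceiling(3 * r_vox / pitch_z))
      for (f in seq_len(n_filaments)) {
        a <- sample.int(n_nodes, 1)
        d2 <- (px - px[a])^2 + (py - py[a])^2
        d2[a] <- Inf
        b <- order(d2)[sample.int(min(3L, n_nodes - 1L), 1)]
        seg_len <- sqrt(d2[b])
        n_samp <- max(2L, ceiling(seg_len / (pitch_xy / 2)))
        tt <- seq(0, 1, length.out = n_samp)
        sx <- px[a] + tt * (px[b] - px[a])
        sy <- py[a] + tt * (py[b] - py[a])
        amp_f <- amplitude * stats::runif(1, 0.6, 1)
        for (s in seq_len(n_samp)) {
          zc <- surface_at(sx[s], sy[s])
          ci <- round(sx[s] / pitch_xy) + 1L
          ri <- round(sy[s] / pitch_xy) + 1L
          pi0 <- round(zc / pitch_z) + 1L
          cr <- max(1L, ci - half):min(nx, ci + half)
          rr <- max(1L, ri - half):min(ny, ri + half)
          pr <- max(1L, pi0 - half_z):min(nz, pi0 + half_z)
          dx <- (cr - 1) * pitch_xy - sx[s]
          dy <- (rr - 1) * pitch_xy - sy[s]
          dz <- (pr - 1) * pitch_z - zc
          g <- amp_f * exp(-(outer(dy^2, dx^2, "+")) / (2 * r_vox^2))
          for (k in seq_along(pr)) {
            w <- exp(-dz[k]^2 / (2 * r_vox^2))
            blk <- arr[rr, cr, pr[k]]
            arr[rr, cr, pr[k]] <- pmax(blk, background + g * w)
          }
        }
      }
      # cell-body puncta at the mesh nodes: bright blobs that anchor the
      # otherwise quasi-regular filament lattice
      for (q in seq_len(n_nodes)) {
        zc <- surface_at(px[q], py[q])
        rq <- node_r[q]
        halfq <- max(1L, ceiling(3 * rq / pitch_xy))
        halfqz <- max(1L, ceiling(3 * rq / pitch_z))
        ci <- round(px[q] / pitch_xy) + 1L
        ri <- round(py[q] / pitch_xy) + 1L
        pi0 <- round(zc / pitch_z) + 1L
        cr <- max(1L, ci - halfq):min(nx, ci + halfq)
        rr <- max(1L, ri - halfq):min(ny, ri + halfq)
        pr <- max(1L, pi0 - halfqz):min(nz, pi0 + halfqz)
        dx <- (cr - 1) * pitch_xy - px[q]
        dy <- (rr - 1) * pitch_xy - py[q]
        dz <- (pr - 1) * pitch_z - zc
        g <- node_amp[q] * exp(-(outer(dy^2, dx^2, "+")) / (2 * rq^2))
        for (k in seq_along(pr)) {
          w <- exp(-dz[k]^2 / (2 * rq^2))
          blk <- arr[rr, cr, pr[k]]
          arr[rr, cr, pr[k]] <- pmax(blk, background + g * w)
        }
      }
    }
    arr
  })
  specimen_volume(vol, pitch_xy = pitch_xy, pitch_z = pitch_z,
                  origin = origin_um)
}

#' Render a synthetic USAF 1951 resolution target
#'
#' Draws three-bar elements (dark bars on a bright field, both orientations)
#' for the requested groups at the stated line-pair spacing, and returns the
#' image together with a geometry table giving each element's bounding box
#' and exact bar geometry in pixels. Spacing follows the standard chart
#' indexing: `RES_LP = 2^(group + (element - 1) / 6)` line pairs per mm, so
#' the line-pair period is `1000 / RES_LP` µm.
#'
#' @param max_group Largest (finest) group to draw.
#' @param pixel_um Image pixel size, µm.
#' @param min_group Smallest group to draw (default: `max_group`, one group
#'   column; real charts nest many groups but coarse groups dominate the
#'   canvas size).
#' @param bright,dark Field and bar intensities (pattern is binary before
#'   any optical blur).
#' @return A list with `image` (matrix, row 1 = minimum Y) and `geometry`
#'   (data.frame: group, element, orientation, res_lp_mm, period_um,
#'   period_px, bar_width_px, and bounding box row0/row1/col0/col1).
#' @export
make_usaf_target <- function(max_group, pixel_um, min_group = max_group,
                             bright = 1, dark = 0) {
  if (min_group > max_group) stop("`min_group` must be <= `max_group`")
  groups <- seq(min_group, max_group)
  finest_lp <- res_lp(max_group, 6L)
  finest_bar_px <- (500 / finest_lp) / pixel_um
  if (finest_bar_px < 2) {
    ok <- expand.grid(element = 1:6, group = groups)
    ok$bar_px <- (500 / res_lp(ok$group, ok$element)) / pixel_um
    ok <- ok[ok$bar_px >= 2, ]
    if (nrow(ok) == 0)
      stop(sprintf("pixel size %.3f µm undersamples every requested element (need >= 2 px per line)",
                   pixel_um))
    best <- ok[which.max(res_lp(ok$group, ok$element)), ]
    stop(sprintf(
      "pixel size %.3f µm undersamples group %d element 6; finest resolvable element is group %d element %d",
      pixel_um, max_group, best$group, best$element))
  }

  blocks <- list()
  for (g in groups) for (e in 1:6) {
    lp <- res_lp(g, e)
    w_px <- (500 / lp) / pixel_um        # bar (and gap) width
    len_px <- 5 * w_px                   # standard 5:1 bar length
    blocks[[length(blocks) + 1]] <- list(group = g, element = e, lp = lp,
                                         w = w_px, len = len_px)
  }
  margin <- ceiling(3 * blocks[[1]]$w)
  col_w <- ceiling(max(vapply(blocks, function(b) 2 * b$len + b$w, 0))) + 2 * margin
  # one column of 6 elements per group; groups side by side
  geo <- list()
  per_group_h <- function(g) {
    hs <- vapply(blocks[vapply(blocks, `[[`, 0, "group") == g],
                 function(b) b$len + margin, 0)
    sum(hs) + margin
  }
  H <- ceiling(max(vapply(groups, per_group_h, 0)))
  W <- col_w * length(groups)
  img <- matrix(bright, nrow = H, ncol = W)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    x0 <- (gi - 1) * col_w + margin
    y <- margin
    for (e in 1:6) {
      b <- blocks[[which(vapply(blocks, `[[`, 0, "group") == g &
                         vapply(blocks, `[[`, 0, "element") == e)]]
      # vertical bars: intensity varies along X
      for (bar in 0:2) {
        c0 <- x0 + bar * 2 * b$w
        cols <- which(seq_len(W) - 0.5 >= c0 & seq_len(W) - 0.5 < c0 + b$w)
        rows <- which(seq_len(H) - 0.5 >= y & seq_len(H) - 0.5 < y + b$len)
        img[rows, cols] <- dark
      }
      geo[[length(geo) + 1]] <- data.frame(
        group = g, element = e, orientation = "vertical",
        res_lp_mm = b$lp, period_um = 1000 / b$lp, period_px = 2 * b$w,
        bar_width_px = b$w,
        row0 = floor(y) + 1, row1 = ceiling(y + b$len),
        col0 = floor(x0) + 1, col1 = ceiling(x0 + 5 * b$w))
      # horizontal bars: intensity varies along Y
      xh <- x0 + 5 * b$w + b$w
      for (bar in 0:2) {
        r0 <- y + bar * 2 * b$w
        rows <- which(seq_len(H) - 0.5 >= r0 & seq_len(H) - 0.5 < r0 + b$w)
        cols <- which(seq_len(W) - 0.5 >= xh & seq_len(W) - 0.5 < xh + b$len)
        img[rows, cols] <- dark
      }
      geo[[length(geo) + 1]] <- data.frame(
        group = g, element = e, orientation = "horizontal",
        res_lp_mm = b$lp, period_um = 1000 / b$lp, period_px = 2 * b$w,
        bar_width_px = b$w,
        row0 = floor(y) + 1, row1 = ceiling(y + 5 * b$w),
        col0 = floor(xh) + 1, col1 = ceiling(xh + b$len))
      y <- y + b$len + margin
    }
  }
  list(image = img, geometry = do.call(rbind, geo))
}

#' Render a synthetic slanted-edge image
#'
#' Produces the slanted dark/bright edge used for slant-edge MTF estimation,
#' sampled with an exact pixel-aperture (area) integral, optionally after an
#' exact Gaussian optical blur. The closed-form sampling makes the image a
#' faithful realization of the analytic system MTF
#' `exp(-2 pi^2 sigma^2 f^2) * |sinc(f)|`.
#'
#' @param size_px Image side length in pixels.
#' @param angle_deg Edge tilt off vertical, degrees (typical 2-15).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 = none).
#' @param low,high Intensities on the dark/bright side of the edge.
#' @return Numeric matrix; edge near-vertical, bright side at larger X.
#' @export
make_slant_edge <- function(size_px, angle_deg, blur_sigma_px = 0,
                            low = 0.1, high = 0.9) {
  n <- as.integer(size_px)
  slope <- tan(angle_deg * pi / 180)
  r <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  edge_x <- n / 2 + slope * (r - n / 2)   # edge column (continuous) per row
  if (blur_sigma_px <= 0) {
    # fraction of the pixel [c-1, c] lying beyond the edge
    frac <- pmin(pmax(cc - edge_x, 0), 1)
  } else {
    s <- blur_sigma_px
    gfun <- function(u) {
      z <- u / s
      u * stats::pnorm(z) + s * stats::dnorm(z)
    }
    frac <- gfun(cc - edge_x) - gfun(cc - 1 - edge_x)
  }
  low + (high - low) * frac
}
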