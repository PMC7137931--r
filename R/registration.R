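# Sub-pixel translation registration by normalized phase correlation.
# One registration engine, two consumers: tile stitching and the
# drift/displacement QC measurements.

#' Phase-correlation registration of two equally sized images
#'
#' Estimates the translation of `b`'s content relative to `a` (positive dx =
#' content moved toward larger column index, positive dy = toward larger row
#' index) from the peak of the normalized cross-power spectrum, refined to
#' sub-pixel precision with a 3-point quadratic fit per axis. The peak value
#' of the normalized correlation surface (1 for a perfect cyclic shift) is
#' reported as the confidence.
#'
#' @param a,b Numeric matrices of identical size.
#' @param expected Expected shift `c(dx, dy)` in pixels; the peak is
#'   searched only within `search_radius` of it.
#' @param search_radius Search radius in pixels around `expected`
#'   (default `Inf`, whole plane).
#' @param window Apply a Hann window to the mean-subtracted images before
#'   correlation (reduces edge wrap-around bias for non-cyclic shifts).
#' @param subpixel Refine the integer peak with a quadratic fit.
#' @param lowpass_sigma_px Gaussian weighting of the cross-power spectrum
#'   (pixels in the spatial domain). Plain phase correlation weights all
#'   frequencies equally, so on low-contrast fluorescence frames the
#'   noise-dominated high-frequency band can drown the true peak; the
#'   low-pass concentrates the correlation on the informative band. `0`
#'   disables it.
#' @return List with `shift` (`c(dx, dy)`, pixels) and `confidence` in
#'   `[0, 1]`.
#' @export
phase_correlate <- function(a, b, expected = c(0, 0), search_radius = Inf,
                            window = TRUE, subpixel = TRUE,
                            lowpass_sigma_px = 2) {
  if (!all(dim(a) == dim(b))) stop("images must have identical dimensions")
  nr <- nrow(a); nc <- ncol(a)
  if (nr < 4 || nc < 4) stop("images too small to register")
  a <- a - mean(a); b <- b - mean(b)
  if (window) {
    wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
    wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
    w <- outer(wr, wc)
    a <- a * w; b <- b * w
  }
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Conj(Fa) * Fb
  mag <- Mod(R)
  R <- R / pmax(mag, max(mag) * 1e-12 + .Machine$double.xmin)
  # unsmoothed surface for localization, low-pass-weighted one for search:
  # the smoothing suppresses spurious noise peaks but blurs (and can bias)
  # the true one, so the peak is re-localized and refined on r0
  r0 <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  r <- r0
  if (lowpass_sigma_px > 0) {
    R <- R * gaussian_transfer(nr, nc, lowpass_sigma_px)
    r <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  }

  wrap <- function(idx, n) ((idx %% n) + n) %% n         # 0-based cyclic
  # unwrap a 0-based peak index to the cyclic representative nearest the
  # expected shift (a -192 px shift in a 256 px frame aliases to +64)
  to_signed <- function(i0, n, ex = 0) {
    d <- wrap(i0 - round(ex), n)
    if (d > n / 2) d <- d - n
    round(ex) + d
  }

  if (is.finite(search_radius)) {
    offs <- -ceiling(search_radius):ceiling(search_radius)
    rows0 <- unique(wrap(round(expected[2]) + offs, nr))
    cols0 <- unique(wrap(round(expected[1]) + offs, nc))
    sub <- r[rows0 + 1, cols0 + 1, drop = FALSE]
    k <- arrayInd(which.max(sub), dim(sub))
    pr <- rows0[k[1]]; pc <- cols0[k[2]]
  } else {
    k <- arrayInd(which.max(r), dim(r))
    pr <- k[1] - 1L; pc <- k[2] - 1L
  }
  # re-localize on the unsmoothed surface within a small neighbourhood
  loc <- expand.grid(dr = -2:2, dc = -2:2)
  vals <- mapply(function(dr, dc) r0[wrap(pr + dr, nr) + 1, wrap(pc + dc, nc) + 1],
                 loc$dr, loc$dc)
  kk <- which.max(vals)
  pr <- wrap(pr + loc$dr[kk], nr); pc <- wrap(pc + loc$dc[kk], nc)
  peak <- r0[pr + 1, pc + 1]

  dy <- to_signed(pr, nr, expected[2]); dx <- to_signed(pc, nc, expected[1])
  if (subpixel) {
    dy <- dy + peak_interp(r0[wrap(pr - 1, nr) + 1, pc + 1], peak,
                           r0[wrap(pr + 1, nr) + 1, pc + 1])
    dx <- dx + peak_interp(r0[pr + 1, wrap(pc - 1, nc) + 1], peak,
                           r0[pr + 1, wrap(pc + 1, nc) + 1])
  }
  list(shift = c(dx = dx, dy = dy),
       confidence = max(0, min(1, peak)))
}

# Three-point sub-pixel peak interpolation. The low-pass weighting makes
# the correlation peak Gaussian-shaped, for which the parabola on log
# values is exact; fall back to the plain parabola when a neighbour is
# non-positive.
peak_interp <- function(m1, c0, p1) {
  if (m1 > 0 && c0 > 0 && p1 > 0 && c0 >= m1 && c0 >= p1) {
    lm1 <- log(m1); lc0 <- log(c0); lp1 <- log(p1)
    den <- lm1 - 2 * lc0 + lp1
    if (is.finite(den) && abs(den) > .Machine$double.eps)
      return(max(min(0.5 * (lm1 - lp1) / den, 0.5), -0.5))
  }
  den <- m1 - 2 * c0 + p1
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  max(min(0.5 * (m1 - p1) / den, 0.5), -0.5)
}

#' Estimate the offset between two overlapping tiles
#'
#' Refines a nominal tile offset (position of tile B's origin relative to
#' tile A's origin, in pixels) by whole-frame phase correlation searched
#' around the nominal offset; the nominal offset must still predict a
#' usable (>= 32 px) overlap. A featureless or decorrelated overlap yields
#' a low confidence; the nominal offset is then returned with
#' `fallback = TRUE`.
#'
#' @param imA,imB Tile images (matrices; row = Y, col = X).
#' @param nominal_offset_px Nominal offset `c(dx, dy)`, pixels.
#' @param search_radius_px Maximum deviation from nominal searched, px.
#' @param min_confidence Confidence below which the estimate falls back to
#'   the nominal offset.
#' @return An object of class `offset_estimate`: `dx`, `dy` (pixels,
#'   sub-pixel), `confidence`, `fallback`.
#' @export
pairwise_offset <- function(imA, imB, nominal_offset_px,
                            search_radius_px = 8, min_confidence = 0.15) {
  dx0 <- round(nominal_offset_px[1]); dy0 <- round(nominal_offset_px[2])
  rA <- max(1, 1 + dy0):min(nrow(imA), nrow(imB) + dy0)
  cA <- max(1, 1 + dx0):min(ncol(imA), ncol(imB) + dx0)
  if (length(rA) < 32 || length(cA) < 32)
    stop("overlap region predicted by the nominal offset is narrower than 32 px")
  # expand the nominal overlap by the search radius (zero-filled beyond the
  # image borders) so the true shared content stays inside the correlated
  # window even when the actual offset misses nominal by piezo-scale errors
  R <- ceiling(search_radius_px)
  rE <- (min(rA) - R):(max(rA) + R)
  cE <- (min(cA) - R):(max(cA) + R)
  crop_pad <- function(im, rows, cols) {
    out <- matrix(0, length(rows), length(cols))
    msk <- matrix(FALSE, length(rows), length(cols))
    rok <- rows >= 1 & rows <= nrow(im)
    cok <- cols >= 1 & cols <= ncol(im)
    sub <- im[rows[rok], cols[cok], drop = FALSE]
    out[rok, cok] <- sub - mean(sub)
    msk[rok, cok] <- TRUE
    list(v = out, m = msk)
  }
  cropA <- crop_pad(imA, rE, cE)
  cropB <- crop_pad(imB, rE - dy0, cE - dx0)
  # candidate peaks from phase correlation, verified by direct normalized
  # cross-correlation of the overlap each candidate implies; NCC is the
  # confidence. The crops are high-pass filtered for the verification so
  # smooth background and vignetting (which correlate at any shift) do not
  # mask the structural agreement - this is what makes sparse, noisy
  # fluorescence overlaps register reliably.
  hp <- function(cr) {
    # normalized convolution: the local mean is estimated from valid
    # pixels only, so the zero padding cannot ring into the mask interior
    mnum <- fft_gaussian_blur(cr$v * cr$m, 8)
    mden <- fft_gaussian_blur(cr$m * 1, 8)
    lp <- mnum / pmax(mden, 1e-6)
    list(v = (cr$v - lp) * cr$m, m = cr$m)
  }
  hpA <- hp(cropA); hpB <- hp(cropB)
  cand <- phase_corr_peaks(cropA$v, cropB$v, search_radius_px, n_peaks = 5)
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    ncc <- shift_ncc(hpA, hpB, cand$dy[k], cand$dx[k])
    if (is.null(best) || ncc > best$ncc)
      best <- list(dx = cand$dx[k], dy = cand$dy[k], ncc = ncc)
  }
  # refine by hill-climbing the NCC surface (phase peaks blur under the
  # low-pass and under partial overlap; the NCC of the high-passed crops
  # resolves few-pixel misalignments), then sub-pixel parabola on NCC
  repeat {
    moved <- FALSE
    for (step in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      v <- shift_ncc(hpA, hpB, best$dy + step[1], best$dx + step[2])
      if (v > best$ncc) {
        best <- list(dx = best$dx + step[2], dy = best$dy + step[1], ncc = v)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  quad <- function(m1, c0, p1) {
    den <- m1 - 2 * c0 + p1
    if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
    max(min(0.5 * (m1 - p1) / den, 0.5), -0.5)
  }
  sub_dx <- quad(shift_ncc(hpA, hpB, best$dy, best$dx - 1), best$ncc,
                 shift_ncc(hpA, hpB, best$dy, best$dx + 1))
  sub_dy <- quad(shift_ncc(hpA, hpB, best$dy - 1, best$dx), best$ncc,
                 shift_ncc(hpA, hpB, best$dy + 1, best$dx))
  best$dx <- best$dx + sub_dx
  best$dy <- best$dy + sub_dy
  est <- c(dx0 - best$dx, dy0 - best$dy)  # B origin = nominal - residual shift
  confidence <- max(0, best$ncc)
  fallback <- confidence < min_confidence
  if (fallback) est <- as.numeric(nominal_offset_px)
  structure(list(dx = est[[1]], dy = est[[2]], confidence = confidence,
                 fallback = fallback),
            class = "offset_estimate")
}

# Normalized cross-correlation of the region shared by a and b when b's
# content is a shifted by (dy, dx): b[r + dy, c + dx] pairs with a[r, c].
# a and b are lists with $v (zero-padded values) and $m (validity mask);
# only pixels real in both crops enter the correlation.
shift_ncc <- function(a, b, dy, dx) {
  n <- nrow(a$v); m <- ncol(a$v)
  ra <- max(1, 1 - dy):min(n, n - dy)
  ca <- max(1, 1 - dx):min(m, m - dx)
  if (length(ra) < 8 || length(ca) < 8) return(-1)
  ok <- a$m[ra, ca] & b$m[ra + dy, ca + dx]
  if (sum(ok) < 32 * 32) return(-1)
  av <- a$v[ra, ca][ok]; bv <- b$v[ra + dy, ca + dx][ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(av, bv)
}

# Top local maxima of the phase-correlation surface within the search
# radius, with quadratic sub-pixel refinement per peak. Shares the
# low-pass cross-power weighting of phase_correlate().
phase_corr_peaks <- function(a, b, search_radius, n_peaks = 5,
                             lowpass_sigma_px = 2) {
  nr <- nrow(a); nc <- ncol(a)
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  w <- outer(wr, wc)
  Fa <- stats::fft((a - mean(a)) * w); Fb <- stats::fft((b - mean(b)) * w)
  R <- Conj(Fa) * Fb
  mag <- Mod(R)
  R <- R / pmax(mag, max(mag) * 1e-12 + .Machine$double.xmin)
  if (lowpass_sigma_px > 0)
    R <- R * gaussian_transfer(nr, nc, lowpass_sigma_px)
  r <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  wrap <- function(idx, n) ((idx %% n) + n) %% n
  offs <- -ceiling(search_radius):ceiling(search_radius)
  rows0 <- wrap(offs, nr); cols0 <- wrap(offs, nc)
  sub <- r[rows0 + 1, cols0 + 1, drop = FALSE]
  found <- list()
  for (p in seq_len(n_peaks)) {
    if (all(!is.finite(sub)) || max(sub, na.rm = TRUE) <= -Inf) break
    k <- arrayInd(which.max(sub), dim(sub))
    dy <- offs[k[1]]; dx <- offs[k[2]]
    pr <- rows0[k[1]]; pc <- cols0[k[2]]
    peak <- r[pr + 1, pc + 1]
    sdy <- peak_interp(r[wrap(pr - 1, nr) + 1, pc + 1], peak,
                       r[wrap(pr + 1, nr) + 1, pc + 1])
    sdx <- peak_interp(r[pr + 1, wrap(pc - 1, nc) + 1], peak,
                       r[pr + 1, wrap(pc + 1, nc) + 1])
    found[[p]] <- data.frame(dy = dy, dx = dx, sub_dy = sdy, sub_dx = sdx,
                             value = peak)
    # suppress a neighbourhood around the taken peak
    supp_r <- which(abs(((offs - dy + nr / 2) %% nr) - nr / 2) <= 2)
    supp_c <- which(abs(((offs - dx + nc / 2) %% nc) - nc / 2) <= 2)
    sub[supp_r, supp_c] <- -Inf
  }
  do.call(rbind, found)
}

#' Measure stage displacement between two frames
#'
#' Automates the video-based distance measurement used to characterize the
#' actuators: the sub-pixel image shift between two frames of the same
#' scene, scaled by the pixel size. The reported vector is the displacement
#' of the scene content in frame `b` relative to frame `a`.
#'
#' @param frame_a,frame_b Frames sharing content (matrices).
#' @param pixel_um Pixel size, µm.
#' @param min_confidence Registration confidence below which the result is
#'   flagged.
#' @return Named vector `c(dx_um, dy_um)` with attributes `confidence` and
#'   `flagged`.
#' @export
measure_displacement <- function(frame_a, frame_b, pixel_um,
                                 min_confidence = 0.03) {
  pc <- phase_correlate(frame_a, frame_b)
  out <- c(dx_um = pc$shift[["dx"]] * pixel_um,
           dy_um = pc$shift[["dy"]] * pixel_um)
  attr(out, "confidence") <- pc$confidence
  attr(out, "flagged") <- pc$confidence < min_confidence
  out
}

#' Track drift across a frame series
#'
#' Registers every frame against the first and reports per-frame
#' displacement, reproducing the fixed-corner stability test (a target
#' corner imaged repeatedly over minutes to hours).
#'
#' @param frames List of frames (matrices).
#' @param pixel_um Pixel size, µm.
#' @param timestamps Optional acquisition times (any numeric unit).
#' @return data.frame with columns frame, t, dx_um, dy_um, confidence,
#'   flagged; maximum absolute drift per axis in attribute `max_drift_um`.
#' @export
drift_track <- function(frames, pixel_um, timestamps = NULL) {
  if (length(frames) < 2) stop("need at least 2 frames to track drift")
  if (is.null(timestamps)) timestamps <- seq_along(frames) - 1
  rows <- lapply(seq_along(frames), function(k) {
    if (k == 1)
      return(data.frame(frame = 1L, t = timestamps[1], dx_um = 0, dy_um = 0,
                        confidence = 1, flagged = FALSE))
    d <- measure_displacement(frames[[1]], frames[[k]], pixel_um)
    data.frame(frame = k, t = timestamps[k],
               dx_um = d[["dx_um"]], dy_um = d[["dy_um"]],
               confidence = attr(d, "confidence"),
               flagged = attr(d, "flagged"))
  })
  out <- do.call(rbind, rows)
  attr(out, "max_drift_um") <- c(x = max(abs(out$dx_um)),
                                 y = max(abs(out$dy_um)))
  out
}
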