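#' Camera and optics model for the virtual microscope
#'
#' Bundles the parameters of the simulated imaging path. Defocus is modelled
#' as a Gaussian blur whose sigma grows linearly with distance from the
#' focal plane; vignetting as a radial cosine-fourth-style falloff; noise as
#' Poisson photon noise plus Gaussian read noise.
#'
#' @param na Numerical aperture, in (0, 1].
#' @param wavelength_nm Emission wavelength, nm.
#' @param pixel_um Camera pixel size in specimen units, µm/pixel (0.386 µm
#'   at the reference 20x configuration).
#' @param fov_px Frame width/height in pixels (square frames).
#' @param defocus_blur_um_per_um Blur-kernel sigma growth per µm of defocus
#'   (µm of blur per µm of defocus).
#' @param vignette_strength Relative corner falloff in `[0, 1]`; the default
#'   is mild (5%) since the reference system's illumination is close to
#'   uniform.
#' @param photon_scale Expected photons per intensity unit; Poisson noise is
#'   applied at this scaling (default gives SNR about 20 on unit-intensity
#'   structures). `0` disables photon noise.
#' @param read_noise_sd Gaussian read-noise SD in intensity units; `0`
#'   disables it.
#' @param full_scale Intensity value mapped to sensor saturation.
#' @param bit_depth Output integer depth (default 16); `NA` returns
#'   unquantized floating-point frames (used by analytic test oracles).
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(na = 0.5, wavelength_nm = 530, pixel_um = 0.386,
                         fov_px = 256, defocus_blur_um_per_um = 0.5,
                         vignette_strength = 0.05,
                         photon_scale = 400, read_noise_sd = 0.005,
                         full_scale = 4, bit_depth = 16) {
  if (!(na > 0 && na <= 1)) stop("`na` must be in (0, 1]")
  if (pixel_um <= 0) stop("`pixel_um` must be positive")
  if (vignette_strength < 0 || vignette_strength > 1)
    stop("`vignette_strength` must be in [0, 1]")
  if (fov_px < 8) stop("`fov_px` must be at least 8")
  structure(
    list(na = na, wavelength_nm = wavelength_nm, pixel_um = pixel_um,
         fov_px = as.integer(fov_px),
         defocus_blur_um_per_um = defocus_blur_um_per_um,
         vignette_strength = vignette_strength,
         photon_scale = photon_scale, read_noise_sd = read_noise_sd,
         full_scale = full_scale, bit_depth = bit_depth),
    class = "optics_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf(
    "<optics_model> NA %.2f, %g nm, %.3f µm/px, %d px FOV, blur %.2f µm/µm\n",
    x$na, x$wavelength_nm, x$pixel_um, x$fov_px, x$defocus_blur_um_per_um))
  invisible(x)
}

# Vignette field: cos^4-style radial falloff with the corner at
# (1 - strength) of the centre.
vignette_field <- function(n, strength) {
  if (strength <= 0) return(matrix(1, n, n))
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  d_corner <- sqrt(2) * (ctr - 1)
  a <- acos((1 - strength)^0.25) / d_corner
  cos(pmin(a * d, pi / 2))^4
}

# Per-tile renderer preparation: resample every volume plane onto a padded
# camera grid around the FOV at (x_um, y_um) and cache its FFT. One FFT per
# plane here buys one inverse FFT per frame later, which is what makes
# full-scan simulations tractable.
prepare_tile_render <- function(vol, x_um, y_um, optics, sigma_max_px) {
  fov <- optics$fov_px
  # margin only needs to cover the largest kernel actually convolved; far
  # planes are folded in as their mean (see render_from_cache)
  margin <- min(64L, as.integer(ceiling(3 * sigma_max_px) + 4L))
  n <- next_fft_size(fov + 2L * margin)
  margin <- (n - fov) %/% 2L   # distribute any round-up into the pad
  ext <- specimen_extent(vol)
  fov_um <- fov * optics$pixel_um
  if (x_um >= ext$x[2] || x_um + fov_um <= ext$x[1] ||
      y_um >= ext$y[2] || y_um + fov_um <= ext$y[1])
    stop(sprintf(
      "requested FOV at (%.1f, %.1f) µm lies fully outside the specimen volume",
      x_um, y_um))
  # camera pixel centres on the padded grid, in volume fractional indices
  xs <- x_um + (seq_len(n) - 0.5 - margin) * optics$pixel_um
  ys <- y_um + (seq_len(n) - 0.5 - margin) * optics$pixel_um
  cols <- (xs - vol$origin[1]) / vol$pitch_xy + 1
  rows <- (ys - vol$origin[2]) / vol$pitch_xy + 1
  nzp <- dim(vol$intensity)[3]
  plane_fft <- vector("list", nzp)
  for (p in seq_len(nzp)) {
    plane <- bilinear_grid(vol$intensity[, , p], rows, cols)
    plane_fft[[p]] <- stats::fft(plane)
  }
  list(n = n, margin = margin, fov = fov, plane_fft = plane_fft,
       z_planes = vol$origin[3] + (seq_len(nzp) - 1) * vol$pitch_z,
       pitch_z = vol$pitch_z)
}

# Render one frame from a prepared tile cache at focal depth z_um.
# Returns the noiseless, vignette-free floating-point frame. Planes blurred
# beyond `uniform_sigma_px` are indistinguishable from their mean at frame
# scale and are added as a constant, which keeps full-scan simulations fast
# without disturbing the energy balance.
render_from_cache <- function(prep, z_um, optics, uniform_sigma_px = 30) {
  acc <- matrix(0 + 0i, prep$n, prep$n)
  dc <- 0
  for (p in seq_along(prep$plane_fft)) {
    sigma_um <- abs(prep$z_planes[p] - z_um) * optics$defocus_blur_um_per_um
    sigma_px <- sigma_um / optics$pixel_um
    if (sigma_px > uniform_sigma_px) {
      dc <- dc + Re(prep$plane_fft[[p]][1, 1]) / (prep$n^2)
    } else {
      acc <- acc + prep$plane_fft[[p]] * gaussian_transfer(prep$n, prep$n, sigma_px)
    }
  }
  fr <- Re(stats::fft(acc, inverse = TRUE)) / (prep$n^2) + dc
  i0 <- prep$margin
  fr[(i0 + 1):(i0 + prep$fov), (i0 + 1):(i0 + prep$fov)]
}

# Apply vignette, noise and quantization; deterministic for a fixed seed.
finish_frame <- function(fr, optics, seed) {
  fr <- fr * vignette_field(optics$fov_px, optics$vignette_strength)
  if (optics$photon_scale > 0 || optics$read_noise_sd > 0) {
    fr <- with_seed(seed, {
      out <- fr
      if (optics$photon_scale > 0)
        out <- stats::rpois(length(out), pmax(out, 0) * optics$photon_scale) /
          optics$photon_scale
      if (optics$read_noise_sd > 0)
        out <- out + stats::rnorm(length(out), 0, optics$read_noise_sd)
      matrix(out, nrow(fr), ncol(fr))
    })
  }
  if (is.na(optics$bit_depth)) return(fr)
  top <- 2^optics$bit_depth - 1
  dn <- round(fr / optics$full_scale * top)
  matrix(pmin(pmax(dn, 0), top), nrow(fr), ncol(fr))
}

# Largest defocus sigma (px) over a set of focal depths for a volume.
max_defocus_sigma_px <- function(vol, z_values, optics) {
  ext <- specimen_extent(vol)
  dmax <- max(abs(outer(ext$z, z_values, "-")))
  dmax * optics$defocus_blur_um_per_um / optics$pixel_um
}

#' Render a camera frame of a specimen volume
#'
#' Simulates one exposure: every volume plane is resampled onto the camera
#' grid, blurred with a Gaussian whose sigma is proportional to its distance
#' from the focal plane, and summed; the sum is vignetted, noised and
#' quantized according to the optics model. The stage position gives the
#' physical location of the frame's minimum-X/minimum-Y corner and the
#' focal depth: `pos = c(x, y, z)` µm, with larger z focusing deeper.
#'
#' @param vol A [specimen_volume()].
#' @param pos Stage position `c(x, y, z)`, µm.
#' @param optics An [optics_model()].
#' @param seed Integer seed for the noise draw; frames are identical for
#'   identical `pos`/`seed`.
#' @return `fov_px` x `fov_px` matrix (integer digital numbers, or float if
#'   `bit_depth` is `NA`), row 1 = minimum Y.
#' @export
render_frame <- function(vol, pos, optics, seed = 1L) {
  if (length(pos) != 3) stop("`pos` must be c(x, y, z) in µm")
  smax <- max_defocus_sigma_px(vol, pos[3], optics)
  prep <- prepare_tile_render(vol, pos[1], pos[2], optics, smax)
  finish_frame(render_from_cache(prep, pos[3], optics), optics, seed)
}

#' Render a Z-stack of frames at one XY position
#'
#' Shares the per-plane resampling work across all frames of the stack;
#' otherwise identical to calling [render_frame()] per focal depth.
#'
#' @param vol A [specimen_volume()].
#' @param xy Stage XY position `c(x, y)`, µm.
#' @param z_um Vector of focal depths, µm.
#' @param optics An [optics_model()].
#' @param seed Integer seed; expanded into one child seed per frame.
#' @return List of frames (matrices), one per focal depth.
#' @export
render_stack <- function(vol, xy, z_um, optics, seed = 1L) {
  smax <- max_defocus_sigma_px(vol, z_um, optics)
  prep <- prepare_tile_render(vol, xy[1], xy[2], optics, smax)
  seeds <- derive_seeds(seed, length(z_um))
  lapply(seq_along(z_um), function(k)
    finish_frame(render_from_cache(prep, z_um[k], optics), optics, seeds[k]))
}
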