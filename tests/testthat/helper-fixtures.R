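# Shared fixtures, all built in code at test time.

# Noise-free, vignette-free float optics for analytic checks.
clean_optics <- function(fov_px = 128, ...) {
  optics_model(fov_px = fov_px, photon_scale = 0, read_noise_sd = 0,
               vignette_strength = 0, bit_depth = NA, ...)
}

# Small nerve-net volume reused across rendering tests.
small_nervenet <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_nervenet_specimen(c(200, 200, 40), 20, seed = 7,
                                       origin_um = c(0, 0, 50))
    cache
  }
})

# A flat specimen: one textured plane at a known depth, for focus tests.
flat_specimen <- function(z_um = 20, extent = 150, seed = 5) {
  nx <- extent + 1
  nz <- 17
  arr <- array(0.02, dim = c(nx, nx, nz))
  tex <- with_test_seed(seed, matrix(runif(nx * nx), nx, nx))
  p <- round(z_um / 2.5) + 1
  arr[, , p] <- 0.02 + tex
  specimen_volume(arr, pitch_xy = 1, pitch_z = 2.5)
}

# A plane tilted along X: surface depth rises linearly across the extent.
tilted_specimen <- function(extent_x = 600, extent_y = 80, z0 = 60,
                            slope = 0.06, seed = 9) {
  nx <- extent_x + 1; ny <- extent_y + 1
  zmax <- z0 + slope * extent_x + 10
  nz <- ceiling(zmax / 2.5) + 2
  arr <- array(0.02, dim = c(ny, nx, nz))
  tex <- with_test_seed(seed, matrix(runif(ny * nx) > 0.7, ny, nx)) * 1.0
  for (c in seq_len(nx)) {
    z <- z0 + slope * (c - 1)
    p <- round(z / 2.5) + 1
    arr[, c, p] <- 0.02 + tex[, c]
  }
  specimen_volume(arr, pitch_xy = 1, pitch_z = 2.5)
}

# Deterministic RNG scope for fixture construction.
with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Smooth random texture image (band-limited noise) for registration tests.
smooth_texture <- function(n, seed = 1, sigma = 3) {
  raw <- with_test_seed(seed, matrix(rnorm(n * n), n, n))
  G <- exp(-2 * pi^2 * sigma^2 *
             outer(stagescan:::fft_freq(n)^2, stagescan:::fft_freq(n)^2, "+"))
  Re(stats::fft(stats::fft(raw) * G, inverse = TRUE)) / (n * n)
}

default_piezo_stage <- function(origin = c(x = 60, y = 60, z = 63)) {
  stage_state(list(x = actuator_model("piezo"), y = actuator_model("piezo"),
                   z = actuator_model("piezo")), origin = origin)
}

ideal_stepper_stage <- function(origin = c(x = 0, y = 0, z = 0)) {
  stage_state(list(x = actuator_model("stepper"), y = actuator_model("stepper"),
                   z = actuator_model("stepper")), origin = origin)
}
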