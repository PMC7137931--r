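#' USAF 1951 chart resolution in line pairs per mm
#'
#' `RES_LP = 2^(group + (element - 1) / 6)`: each group doubles the spatial
#' frequency and its six elements subdivide the doubling in sixth-octave
#' steps. Group 7 element 6 — the finest element on standard charts —
#' evaluates to 228.07, conventionally reported as 228 lp/mm.
#'
#' @param group Integer group index (negative groups allowed).
#' @param element Element index, integer 1..6.
#' @return Line pairs per mm.
#' @export
res_lp <- function(group, element) {
  if (any(element != round(element)) || any(element < 1) || any(element > 6))
    stop("`element` must be an integer in 1..6")
  if (any(group != round(group))) stop("`group` must be integer")
  2^(group + (element - 1) / 6)
}

#' Line-pair spacing from chart resolution
#'
#' `RES_CC = 1000 / RES_LP`: the centre-to-centre distance between line
#' pairs in µm. (Note: at 228 lp/mm this is 4.39 µm — a line pair period,
#' of which each line is half.)
#'
#' @param res_lp_mm Resolution in line pairs per mm (> 0).
#' @return Spacing in µm.
#' @export
res_cc <- function(res_lp_mm) {
  if (any(res_lp_mm <= 0)) stop("`res_lp_mm` must be > 0")
  1000 / res_lp_mm
}

#' Abbe diffraction limit
#'
#' `d = lambda / (2 NA)`. At NA 0.5 the limit equals the wavelength.
#'
#' @param wavelength_nm Wavelength, nm.
#' @param na Numerical aperture (> 0).
#' @return Limit in nm.
#' @export
abbe_limit <- function(wavelength_nm, na) {
  if (any(na <= 0)) stop("`na` must be > 0")
  wavelength_nm / (2 * na)
}

#' Rayleigh resolution limit
#'
#' 1.22 times the Abbe limit (646.6 nm for 530 nm light at NA 0.5).
#'
#' @inheritParams abbe_limit
#' @return Limit in nm.
#' @export
rayleigh_limit <- function(wavelength_nm, na) {
  1.22 * abbe_limit(wavelength_nm, na)
}

#' Illumination uniformity report
#'
#' Fits a smooth low-order (quadratic) surface to a flat-field image and
#' reports the corner-to-centre intensity ratio and the coefficient of
#' variation of the fitted surface. Both metrics are invariant to a global
#' intensity scale.
#'
#' @param image Single-channel flat-field image (matrix).
#' @return List: `corner_centre_ratio`, `cv`, `fit` (fitted surface).
#' @export
illumination_uniformity <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  r <- (matrix(seq_len(nr), nr, nc) - (nr + 1) / 2) / nr
  cc <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - (nc + 1) / 2) / nc
  X <- cbind(1, as.vector(r), as.vector(cc), as.vector(r)^2,
             as.vector(cc)^2, as.vector(r) * as.vector(cc))
  beta <- qr.solve(X, as.vector(image))
  fit <- matrix(X %*% beta, nr, nc)
  centre <- fit[round((nr + 1) / 2), round((nc + 1) / 2)]
  corners <- mean(c(fit[1, 1], fit[1, nc], fit[nr, 1], fit[nr, nc]))
  list(corner_centre_ratio = corners / centre,
       cv = stats::sd(fit) / mean(fit),
       fit = fit)
}
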