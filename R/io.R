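# File I/O: TIFF images/stacks with JSON sidecar metadata, CSV tables,
# and deterministic object hashing for manifests.

#' Deterministic hash of an R object
#'
#' Canonical-JSON serialization (sorted keys) hashed with MD5; used for the
#' config hash recorded in every manifest so a run can be matched to the
#' exact configuration that produced it.
#'
#' @param x A JSON-serializable object.
#' @return Hex digest string.
#' @export
hash_object <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  # sort keys for stability
  canon <- jsonlite::toJSON(jsonlite::fromJSON(js, simplifyVector = FALSE),
                            auto_unbox = TRUE, digits = NA, pretty = FALSE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(as.character(canon), tmp, eos = NULL)
  unname(tools::md5sum(tmp))
}

#' Write an image or stack as (multi-page) TIFF
#'
#' Integer images are scaled by the bit depth to the `[0, 1]` range the
#' TIFF writer expects; a list of planes becomes a multi-page TIFF.
#'
#' @param image Matrix, or list of matrices (stack).
#' @param path Output path.
#' @param bit_depth Source integer depth (16 by default); `NA` writes
#'   32-bit float.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, bit_depth = 16) {
  planes <- if (is.list(image)) image else list(image)
  if (is.na(bit_depth)) {
    tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    top <- 2^bit_depth - 1
    planes <- lapply(planes, function(p) pmin(pmax(p / top, 0), 1))
    bps <- if (bit_depth <= 8) 8L else 16L
    tiff::writeTIFF(planes, path, bits.per.sample = bps, reduce = FALSE)
  }
  invisible(path)
}

#' Read a (multi-page) TIFF written by [write_image_tiff()]
#'
#' @param path TIFF path.
#' @param bit_depth Integer depth used when writing (values are rescaled
#'   back to digital numbers); `NA` reads float data unscaled.
#' @return Matrix (single page) or list of matrices.
#' @export
read_image_tiff <- function(path, bit_depth = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.na(bit_depth))
    pages <- lapply(pages, function(p) round(p * (2^bit_depth - 1)))
  if (length(pages) == 1) pages[[1]] else pages
}

#' Write a specimen volume as multi-page TIFF plus JSON sidecar
#'
#' Planes are stored normalized to the volume maximum; the sidecar
#' (`<path>.json`) records the pitch, origin and intensity scale needed to
#' reconstruct the physical volume.
#'
#' @param vol A [specimen_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_specimen_tiff <- function(vol, path) {
  top <- max(vol$intensity)
  if (top <= 0) top <- 1
  planes <- lapply(seq_len(dim(vol$intensity)[3]),
                   function(p) vol$intensity[, , p] / top)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(pitch_xy = vol$pitch_xy, pitch_z = vol$pitch_z,
         origin = vol$origin, intensity_scale = top,
         dim = dim(vol$intensity)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a specimen volume written by [write_specimen_tiff()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return A [specimen_volume()].
#' @export
read_specimen_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = meta$dim)
  for (p in seq_along(pages)) arr[, , p] <- pages[[p]] * meta$intensity_scale
  specimen_volume(arr, pitch_xy = meta$pitch_xy, pitch_z = meta$pitch_z,
                  origin = meta$origin)
}

#' Write a gcode program to file
#' @param program A `gcode_program` from [to_gcode()].
#' @param path Output path (conventionally `.gcode`).
#' @return `path`, invisibly.
#' @export
write_gcode <- function(program, path) {
  writeLines(program$lines, path)
  invisible(path)
}
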