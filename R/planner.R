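#' Plan a serpentine tile scan
#'
#' Builds the ordered serpentine (boustrophedon) grid of nominal stage
#' targets: the stage is moved along X `nx` times, then once in Y, then
#' back along X in the opposite direction, until all `nx * ny` fields of
#' view are covered. The tile pitch is `fov * (1 - overlap)` per axis, so
#' adjacent tiles share `overlap` of their field of view. The first row
#' scans in +X from the origin.
#'
#' @param nx,ny Tile counts along X and Y (>= 1).
#' @param fov_um Field-of-view size in µm; length 1 (square) or 2 `(x, y)`.
#' @param overlap_x,overlap_y Fraction of FOV shared by adjacent tiles, in
#'   `[0, 1)` (25% in X and 30% in Y at the reference 20x piezo
#'   configuration; 10% for the stepper stage).
#' @param origin Stage position `c(x, y)` of tile (0, 0), µm.
#' @param nz,dz_um,z_start Z-stack sub-plan carried with the scan plan:
#'   planes per stack, Z step (µm), and first focal depth (µm).
#' @return An object of class `scan_plan`: tile table (`$tiles` with
#'   0-based grid indices i, j, nominal x/y in µm, row direction), pitches,
#'   and the Z sub-plan.
#' @export
plan_serpentine <- function(nx, ny, fov_um, overlap_x = 0.25,
                            overlap_y = 0.30, origin = c(0, 0),
                            nz = 1, dz_um = 0, z_start = 0) {
  if (nx < 1 || ny < 1) stop("`nx` and `ny` must be >= 1")
  if (overlap_x < 0 || overlap_x >= 1 || overlap_y < 0 || overlap_y >= 1)
    stop("overlaps must be in [0, 1)")
  fov_um <- rep(as.numeric(fov_um), length.out = 2)
  pitch_x <- fov_um[1] * (1 - overlap_x)
  pitch_y <- fov_um[2] * (1 - overlap_y)
  tiles <- do.call(rbind, lapply(seq_len(ny) - 1L, function(j) {
    is <- seq_len(nx) - 1L
    if (j %% 2L == 1L) is <- rev(is)   # odd rows run in -X
    data.frame(i = is, j = j,
               x_um = origin[1] + is * pitch_x,
               y_um = origin[2] + j * pitch_y,
               dir = if (j %% 2L == 0L) 1L else -1L)
  }))
  tiles$tile <- seq_len(nrow(tiles))
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), fov_um = fov_um,
         overlap_x = overlap_x, overlap_y = overlap_y,
         pitch_x = pitch_x, pitch_y = pitch_y,
         origin = as.numeric(origin),
         nz = as.integer(nz), dz_um = dz_um, z_start = z_start,
         tiles = tiles[, c("tile", "i", "j", "x_um", "y_um", "dir")]),
    class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf(
    "<scan_plan> %d x %d tiles, FOV %.1f x %.1f µm, pitch %.1f/%.1f µm (overlap %.0f%%/%.0f%%), %d planes/stack\n",
    x$nx, x$ny, x$fov_um[1], x$fov_um[2], x$pitch_x, x$pitch_y,
    100 * x$overlap_x, 100 * x$overlap_y, x$nz))
  invisible(x)
}

#' Measure nominal tile overlap of a plan
#'
#' The per-axis overlap fraction implied by the nominal tile positions:
#' `(fov - pitch) / fov`.
#'
#' @param plan A [plan_serpentine()] plan.
#' @return Named vector `c(x = , y = )` of overlap fractions.
#' @export
plan_overlap <- function(plan) {
  c(x = (plan$fov_um[1] - plan$pitch_x) / plan$fov_um[1],
    y = (plan$fov_um[2] - plan$pitch_y) / plan$fov_um[2])
}

#' Plan Z-stack focal targets
#'
#' @param nz Number of planes (>= 1).
#' @param dz_um Z step between planes, µm.
#' @param z_start First focal depth, µm.
#' @param descending If `TRUE`, reverse the ordering (targets only, spacing
#'   unchanged).
#' @return Numeric vector of `nz` monotone focal depths.
#' @export
plan_zstack <- function(nz, dz_um, z_start = 0, descending = FALSE) {
  if (nz < 1) stop("`nz` must be >= 1")
  z <- z_start + (seq_len(nz) - 1) * dz_um
  if (descending) rev(z) else z
}

#' Emit a gcode program for a scan plan
#'
#' Translates the plan's nominal tile positions into an absolute-positioning
#' gcode program for the stepper stage: a mode-setting preamble (`G21`
#' millimetre units, `G90` absolute positioning) followed by one `G1` move
#' per tile. Coordinates are written in mm with 4 decimals (0.1 µm), so a
#' round trip through [parse_gcode()] reproduces the plan to 0.1 µm.
#'
#' @param plan A [plan_serpentine()] plan.
#' @param feed_mm_min Feed rate for the moves, mm/min.
#' @return An object of class `gcode_program` (`$lines`, `$units`,
#'   `$positioning`).
#' @export
to_gcode <- function(plan, feed_mm_min = 120) {
  lims <- c(range(plan$tiles$x_um), range(plan$tiles$y_um)) / 1000
  if (any(lims < 0) || any(lims > 13))
    stop("plan coordinates exceed the [0, 13] mm travel range")
  lines <- c("G21 ; millimetre units",
             "G90 ; absolute positioning",
             sprintf("G1 X%.4f Y%.4f F%g",
                     plan$tiles$x_um / 1000, plan$tiles$y_um / 1000,
                     feed_mm_min))
  structure(list(lines = lines, units = "mm", positioning = "absolute"),
            class = "gcode_program")
}

#' @export
print.gcode_program <- function(x, ...) {
  cat("<gcode_program> ", length(x$lines), " lines (", x$units, ", ",
      x$positioning, ")\n", sep = "")
  cat(utils::head(x$lines, 5), sep = "\n")
  if (length(x$lines) > 5) cat("...\n")
  invisible(x)
}

#' Parse a gcode program back into stage positions
#'
#' Understands the subset emitted by [to_gcode()]: `G21`/`G20` unit modes,
#' `G90` absolute / `G91` relative positioning, and `G0`/`G1` moves with
#' X/Y/Z words. Used to verify plan round trips and to drive the simulated
#' stepper stage from program text.
#'
#' @param program A `gcode_program`, or character vector of lines.
#' @return data.frame of visited positions in µm (columns x_um, y_um,
#'   z_um; NA where a move omits an axis in absolute mode carries the
#'   previous value).
#' @export
parse_gcode <- function(program) {
  lines <- if (inherits(program, "gcode_program")) program$lines else program
  unit_scale <- 1000   # mm -> µm
  absolute <- TRUE
  pos <- c(x = 0, y = 0, z = 0)
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    words <- strsplit(ln, "\\s+")[[1]]
    cmd <- toupper(words[1])
    if (cmd == "G21") { unit_scale <- 1000; next }
    if (cmd == "G20") { unit_scale <- 25400; next }
    if (cmd == "G90") { absolute <- TRUE; next }
    if (cmd == "G91") { absolute <- FALSE; next }
    if (cmd %in% c("G0", "G00", "G1", "G01")) {
      for (w in words[-1]) {
        ax <- tolower(substr(w, 1, 1))
        if (!ax %in% c("x", "y", "z")) next
        val <- suppressWarnings(as.numeric(substr(w, 2, nchar(w))))
        if (is.na(val)) stop(sprintf("unparseable gcode word '%s' in: %s", w, ln))
        pos[ax] <- if (absolute) val * unit_scale else pos[ax] + val * unit_scale
      }
      out[[length(out) + 1]] <- pos
      next
    }
    stop(sprintf("unsupported gcode line: %s", ln))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("x_um", "y_um", "z_um")
  df
}

#' Convert a physical distance into actuator command units
#'
#' Looks up the µm-per-unit calibration for the axis and travel direction
#' and rounds to the nearest integer command count, half away from zero.
#'
#' @param distance_um Signed distance, µm.
#' @param calibration Calibration table (see [calibration_table()]).
#' @param axis Axis name.
#' @return Signed integer command units.
#' @export
distance_to_commands <- function(distance_um, calibration, axis) {
  if (distance_um == 0) return(0L)
  direction <- if (distance_um > 0) "up" else "down"
  row <- calibration[calibration$axis == axis &
                       calibration$direction == direction, , drop = FALSE]
  if (nrow(row) == 0)
    stop(sprintf("no calibration entry for axis '%s' direction '%s'",
                 axis, direction))
  as.integer(round_half_away(distance_um / row$um_per_unit[1]))
}
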