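#' Autofocus sharpness score
#'
#' Tenengrad-family focus measure: the mean squared Sobel gradient
#' magnitude over the image interior. Higher is sharper; adding a constant
#' offset to every pixel leaves the score unchanged, and a constant image
#' scores exactly 0. The metric is deliberately simple and pluggable — any
#' function with the same contract can be passed to [run_scan()].
#'
#' @param image Numeric matrix.
#' @return Scalar score >= 0.
#' @export
focus_score <- function(image) {
  if (length(image) == 0) stop("empty image")
  g2 <- sobel_sq(image)
  if (length(g2) == 0) return(0)
  mean(g2)
}

#' Maximum intensity projection of a Z-stack
#'
#' Per-pixel maximum across the planes of a stack, collapsing the 3D
#' content into a single 2D image.
#'
#' @param stack List of equally sized matrices, or a 3D array with planes
#'   along the third dimension.
#' @return Matrix of per-pixel maxima.
#' @export
max_intensity_projection <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  if (!is.list(stack) || length(stack) == 0)
    stop("`stack` must be a non-empty list of planes or a 3D array")
  d <- dim(stack[[1]])
  for (p in stack)
    if (!all(dim(p) == d)) stop("stack planes differ in shape")
  Reduce(pmax, stack)
}

#' Z-correction increment from a completed tile
#'
#' Computes the focal offset to apply before the next tile so that the
#' previous tile's best-focus plane is re-centred in the stack:
#' `(best_index - (nz + 1) / 2) * dz_um` with 1-based plane indices
#' (equivalently `(k0 - (nz - 1) / 2) * dz` for 0-based `k0`). Corrections
#' are accumulated across tiles by [run_scan()], tracking a sloped specimen.
#' A featureless tile (all scores zero) contributes no correction and is
#' flagged with a warning so the carried offset is left unchanged.
#'
#' @param record A tile record (see [run_scan()]) with `$focus_scores` and
#'   `$best_index`, or a numeric vector of focus scores.
#' @param dz_um Z step of the stack, µm.
#' @param nz Planes per stack.
#' @return Offset increment in µm (positive = focus deeper).
#' @export
z_correct <- function(record, dz_um, nz) {
  scores <- if (is.list(record)) record$focus_scores else record
  if (length(scores) == 0) stop("record has no focus scores")
  if (all(scores <= 0)) {
    warning("featureless tile (all focus scores zero); Z-correction unchanged")
    return(0)
  }
  best <- which.max(scores)   # ties break toward the lower plane index
  (best - (nz + 1) / 2) * dz_um
}

#' Acquire one tile: Z-stack, focus scores, MIP
#'
#' Executes the open-loop Z-stack at the stage's current position: from
#' the current focal depth (the stack start, already including any carried
#' Z-correction) the stage steps `dz_um` upward `nz - 1` times, rendering a
#' frame at each true achieved depth after the settle wait, scoring focus
#' per plane, and recording the maximum intensity projection. Frames are
#' only captured after the settle window — never while the stage is in
#' motion. The stage is left at the top of the stack; the scan loop issues
#' the return move.
#'
#' @param stage A [stage_state()] positioned at the tile XY and the stack
#'   start depth.
#' @param vol A [specimen_volume()].
#' @param optics An [optics_model()].
#' @param nz Planes per stack.
#' @param dz_um Z step between planes, µm.
#' @param z_offset Carried Z-correction, µm (recorded in the tile record).
#' @param seed Integer seed (expanded per frame).
#' @param settle_ms Simulated settle wait before each exposure, ms.
#' @param focus_fun Focus metric (default [focus_score()]).
#' @return List: `record` (positions, scores, best index, correction,
#'   settle), `stack` (list of frames), `mip` (matrix), `stage` (updated
#'   state).
#' @export
run_tile <- function(stage, vol, optics, nz, dz_um, z_offset = 0,
                     seed = 1L, settle_ms = 350, focus_fun = focus_score) {
  seeds <- derive_seeds(seed, nz + 1L)
  z_achieved <- numeric(nz)
  z_targets <- stage$pos[["z"]] + (seq_len(nz) - 1) * dz_um
  z_achieved[1] <- stage$pos[["z"]]
  for (k in seq_len(nz)[-1]) {
    stage <- move_by(stage, c(z = dz_um), seed = seeds[k])
    z_achieved[k] <- stage$pos[["z"]]
  }
  frames <- tryCatch(
    render_stack(vol, c(stage$pos[["x"]], stage$pos[["y"]]), z_achieved,
                 optics, seed = seeds[nz + 1L]),
    error = function(e) stop(sprintf("tile at (%.1f, %.1f) µm: %s",
                                     stage$pos[["x"]], stage$pos[["y"]],
                                     conditionMessage(e)), call. = FALSE))
  scores <- vapply(frames, focus_fun, numeric(1))
  best <- which.max(scores)
  list(record = list(x_um = stage$pos[["x"]], y_um = stage$pos[["y"]],
                     z_targets_um = z_targets,
                     z_achieved_um = z_achieved,
                     focus_scores = scores, best_index = best,
                     z_correction_um = z_offset, settle_ms = settle_ms),
       stack = frames,
       mip = max_intensity_projection(frames),
       stage = stage)
}

#' Execute a serpentine scan plan on the virtual microscope
#'
#' Visits every tile of the plan in serpentine order, acquiring a Z-stack
#' and maximum intensity projection per field of view. Motion is open-loop
#' and relative, as on the physical instrument: every tile step issues the
#' plan's pitch as a distance command (it does not re-target from the
#' achieved position), the Z-stack climbs in `dz_um` steps, and a return
#' move brings the stage back to the next stack start. After each tile the
#' autofocus-based Z-correction adjusts that return move so the stack stays
#' centred on the specimen (cumulative, so a sloped specimen — or the
#' systematic up/down travel asymmetry of a piezo Z axis — is tracked
#' instead of drifting out of focus). The returned
#' manifest records nominal and achieved positions, focus scores, applied
#' corrections, seeds and a configuration hash — enough to re-run the scan
#' exactly. If `out_dir` is given, MIPs (and optionally raw stacks) are
#' written as TIFF with the manifest as JSON; a mid-scan failure still
#' writes the manifest with the completed tiles and a failure marker.
#'
#' @param plan A [plan_serpentine()] plan (with its Z sub-plan).
#' @param vol A [specimen_volume()].
#' @param optics An [optics_model()].
#' @param stage A [stage_state()]; its travel must contain the plan.
#' @param seed Integer master seed, expanded per tile.
#' @param z_correct_enabled Apply inter-tile Z-correction (default TRUE).
#' @param settle_ms Settle wait before each exposure, ms.
#' @param out_dir Optional output directory for TIFFs and manifest.
#' @param keep_stacks Keep raw stacks in the result (and write them when
#'   `out_dir` is set); MIPs are always kept.
#' @param focus_fun Focus metric (default [focus_score()]).
#' @return An object of class `scan_result`: `tiles` (list of tile
#'   records), `mips` (list of matrices), `stacks` (if kept), `manifest`.
#' @export
run_scan <- function(plan, vol, optics, stage, seed = 1L,
                     z_correct_enabled = TRUE, settle_ms = 350,
                     out_dir = NULL, keep_stacks = FALSE,
                     focus_fun = focus_score) {
  tl <- plan$tiles
  for (ax in c("x", "y")) {
    vals <- if (ax == "x") tl$x_um else tl$y_um
    lim <- stage$actuators[[ax]]$travel_um
    if (any(vals < 0) || any(vals > lim))
      stop(sprintf("plan does not fit within the stage's %s travel [0, %g] µm",
                   ax, lim))
  }
  seeds <- derive_seeds(seed, nrow(tl) * 3L + 1L)
  cfg_hash <- hash_object(list(plan = unclass(plan), optics = unclass(optics),
                               seed = seed, z_correct = z_correct_enabled,
                               settle_ms = settle_ms))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  records <- vector("list", nrow(tl))
  mips <- vector("list", nrow(tl))
  stacks <- if (keep_stacks) vector("list", nrow(tl)) else NULL
  z_offset <- 0
  failure <- NULL
  n_frames <- 0L
  # position the stage at the first tile and the stack start (set-up move)
  stage <- move_to(stage, c(x = tl$x_um[1], y = tl$y_um[1],
                            z = plan$z_start), seed = seeds[length(seeds)])
  for (t in seq_len(nrow(tl))) {
    res <- tryCatch({
      if (t > 1)
        stage <- move_by(stage, c(x = tl$x_um[t] - tl$x_um[t - 1],
                                  y = tl$y_um[t] - tl$y_um[t - 1]),
                         seed = seeds[3 * t - 2])
      run_tile(stage, vol, optics, plan$nz, plan$dz_um, z_offset,
               seed = seeds[3 * t - 1], settle_ms = settle_ms,
               focus_fun = focus_fun)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failure <- sprintf("tile %d (i=%d, j=%d): %s", t, tl$i[t], tl$j[t],
                         conditionMessage(res))
      break
    }
    stage <- res$stage
    rec <- res$record
    rec$tile <- t; rec$i <- tl$i[t]; rec$j <- tl$j[t]
    rec$nominal_x_um <- tl$x_um[t]; rec$nominal_y_um <- tl$y_um[t]
    n_frames <- n_frames + length(res$stack)
    if (!is.null(out_dir)) {
      mip_file <- sprintf("tile_j%02d_i%02d_mip.tif", tl$j[t], tl$i[t])
      write_image_tiff(res$mip, file.path(out_dir, mip_file), optics$bit_depth)
      rec$mip_file <- mip_file
      if (keep_stacks) {
        stack_file <- sprintf("tile_j%02d_i%02d.tif", tl$j[t], tl$i[t])
        write_image_tiff(res$stack, file.path(out_dir, stack_file),
                         optics$bit_depth)
        rec$stack_file <- stack_file
      }
    }
    records[[t]] <- rec
    mips[[t]] <- res$mip
    if (keep_stacks) stacks[[t]] <- res$stack
    inc <- 0
    if (z_correct_enabled) {
      inc <- withCallingHandlers(
        z_correct(rec, plan$dz_um, plan$nz),
        warning = function(w) invokeRestart("muffleWarning"))
      z_offset <- z_offset + inc
    }
    # return move: back down the stack, plus this tile's correction
    stage <- move_by(stage, c(z = -(plan$nz - 1) * plan$dz_um + inc),
                     seed = seeds[3 * t])
  }
  done <- !vapply(records, is.null, logical(1))
  manifest <- list(
    plan = list(nx = plan$nx, ny = plan$ny, fov_um = plan$fov_um,
                overlap_x = plan$overlap_x, overlap_y = plan$overlap_y,
                nz = plan$nz, dz_um = plan$dz_um, z_start = plan$z_start,
                origin = plan$origin),
    seed = seed, config_hash = cfg_hash,
    z_correct = z_correct_enabled, settle_ms = settle_ms,
    n_tiles_planned = nrow(tl), n_tiles_done = sum(done),
    n_frames = n_frames,
    failure = failure,
    tiles = records[done])
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(tiles = records[done], mips = mips[done],
                 stacks = if (keep_stacks) stacks[done] else NULL,
                 manifest = manifest, stage = stage),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<scan_result> %d/%d tiles, %d raw frames%s\n",
              m$n_tiles_done, m$n_tiles_planned, m$n_frames,
              if (is.null(m$failure)) "" else paste0(" [FAILED: ", m$failure, "]")))
  invisible(x)
}
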