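#' Actuator step-size calibration statistics
#'
#' Reduces repeated displacement measurements — one row per executed step
#' command, grouped by axis, travel direction and commanded step size — to
#' the calibration summary used throughout: per-group mean and standard
#' deviation (SD only when n >= 2, matching the convention that single or
#' unresolvable repeats report a mean only), and a per-axis/direction
#' µm-per-unit slope fitted by least squares through the origin across step
#' sizes (zero command producing zero displacement is physical).
#'
#' @param measurements data.frame with columns `axis`, `direction`
#'   (`"up"`/`"down"`), `step_size` (command units) and `distance_um`
#'   (measured displacement magnitude, µm), one row per repeat.
#' @return An object of class `step_calibration`: `records` (per
#'   axis/direction/step_size: n, mean_um, sd_um) and `slopes` (per
#'   axis/direction: um_per_unit, se, n).
#' @export
calibrate_steps <- function(measurements) {
  req <- c("axis", "direction", "step_size", "distance_um")
  if (!all(req %in% names(measurements)))
    stop("`measurements` needs columns axis, direction, step_size, distance_um")
  m <- measurements[!is.na(measurements$distance_um), , drop = FALSE]
  if (nrow(m) < nrow(measurements))
    warning("dropped rows with missing distance_um")
  if (nrow(m) == 0) stop("no usable measurements")

  key <- interaction(m$axis, m$direction, m$step_size, drop = TRUE)
  records <- do.call(rbind, lapply(split(m, key), function(g) {
    data.frame(axis = g$axis[1], direction = g$direction[1],
               step_size = g$step_size[1], n = nrow(g),
               mean_um = mean(g$distance_um),
               sd_um = if (nrow(g) >= 2) stats::sd(g$distance_um) else NA_real_)
  }))
  records <- records[order(records$axis, records$direction, records$step_size), ]
  rownames(records) <- NULL

  key2 <- interaction(m$axis, m$direction, drop = TRUE)
  slopes <- do.call(rbind, lapply(split(m, key2), function(g) {
    x <- g$step_size; y <- g$distance_um
    slope <- sum(x * y) / sum(x^2)
    resid <- y - slope * x
    se <- if (nrow(g) >= 2)
      sqrt(sum(resid^2) / (nrow(g) - 1) / sum(x^2)) else NA_real_
    data.frame(axis = g$axis[1], direction = g$direction[1],
               um_per_unit = slope, se = se, n = nrow(g))
  }))
  rownames(slopes) <- NULL
  structure(list(records = records, slopes = slopes),
            class = "step_calibration")
}

#' @export
print.step_calibration <- function(x, ...) {
  cat("<step_calibration>\n")
  print(x$slopes)
  invisible(x)
}

#' Convert a step calibration into a stage calibration table
#'
#' Extracts the per-axis, per-direction µm-per-unit slopes in the format
#' [move_to()] consumes, so a stage can be driven with a measured (rather
#' than nominal) calibration.
#'
#' @param calibration A [calibrate_steps()] result.
#' @return data.frame with columns axis, direction, um_per_unit.
#' @export
as_calibration_table <- function(calibration) {
  stopifnot(inherits(calibration, "step_calibration"))
  calibration$slopes[, c("axis", "direction", "um_per_unit")]
}

#' Simulate a step-size calibration experiment
#'
#' Runs the video-measurement protocol against a virtual actuator: each of
#' the commanded step sizes is executed `n_repeats` times in each
#' direction and the per-repeat displacement magnitude recorded. The
#' default step sizes and repeat count follow the reference protocol
#' (1000, 500, 250, 50, 20 command units, n = 15).
#'
#' @param model An [actuator_model()].
#' @param step_sizes Commanded step sizes (units).
#' @param n_repeats Repeats per step size and direction.
#' @param axis Axis label for the output table.
#' @param seed Integer seed.
#' @return data.frame in the format [calibrate_steps()] accepts (plus a
#'   `repeat_id` column).
#' @export
simulate_step_measurements <- function(model,
                                       step_sizes = c(1000, 500, 250, 50, 20),
                                       n_repeats = 15, axis = "z",
                                       seed = 1L) {
  seeds <- derive_seeds(seed, 2L * length(step_sizes) * n_repeats)
  k <- 0L
  rows <- list()
  for (dir in c("up", "down")) for (s in step_sizes) for (r in seq_len(n_repeats)) {
    k <- k + 1L
    units <- if (dir == "up") s else -s
    d <- actuate(model, units, seed = seeds[k])
    rows[[k]] <- data.frame(axis = axis, direction = dir, step_size = s,
                            repeat_id = r, distance_um = abs(d))
  }
  do.call(rbind, rows)
}
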