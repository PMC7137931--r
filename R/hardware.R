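#' Parametric actuator motion model
#'
#' Two actuator families drive the virtual stage. Piezoelectric inertial
#' actuators are open-loop friction drives: the displacement per commanded
#' "step size" unit depends on load, direction and drive settings, varies by
#' up to `variability_frac` with every actuation, and travels further up
#' than down by `asymmetry_ratio`. Micrometer-coupled stepper motors are
#' deterministic: the 500 µm/revolution micrometer and 200 steps/revolution
#' motor give exactly 2.5 µm per full step, and 1/16 microstepping gives
#' 156.25 nm per microstep.
#'
#' @param kind `"piezo"` or `"stepper"`.
#' @param nominal_um_per_unit Mean displacement per command unit, µm. For a
#'   piezo this is a per-configuration calibrated constant (the command
#'   units are arbitrary and load-dependent); for a stepper it is the exact
#'   gearing, 0.15625 µm per 1/16 microstep.
#' @param variability_frac Maximum relative deviation per actuation
#'   (uniform on +/- this fraction). Piezo default 0.20; stepper 0.
#' @param asymmetry_ratio Mean up-travel divided by mean down-travel
#'   (piezo default 1.15; stepper 1).
#' @param load_g Attached mass, grams (metadata; the nominal calibration is
#'   per-load).
#' @param travel_um Travel range, µm (13 mm for both stage families).
#' @param coupling_error_frac Fixed relative scale error for steppers
#'   (default 0), mimicking imperfect micrometer coupling.
#' @param settle_amplitude_um,settle_tau_ms,settle_period_ms Residual
#'   post-move oscillation: initial amplitude, exponential decay constant
#'   and oscillation period.
#' @param meta Free-form drive metadata (voltage, drive rate, ...).
#' @return An object of class `actuator_model`.
#' @export
actuator_model <- function(kind = c("piezo", "stepper"),
                           nominal_um_per_unit = NULL,
                           variability_frac = NULL,
                           asymmetry_ratio = NULL,
                           load_g = 335, travel_um = 13000,
                           coupling_error_frac = 0,
                           settle_amplitude_um = 0.5, settle_tau_ms = 60,
                           settle_period_ms = 20,
                           meta = list()) {
  kind <- match.arg(kind)
  if (is.null(nominal_um_per_unit))
    nominal_um_per_unit <- if (kind == "piezo") 0.05 else 0.15625
  if (is.null(variability_frac))
    variability_frac <- if (kind == "piezo") 0.20 else 0
  if (is.null(asymmetry_ratio))
    asymmetry_ratio <- if (kind == "piezo") 1.15 else 1
  if (nominal_um_per_unit <= 0) stop("`nominal_um_per_unit` must be > 0")
  if (variability_frac < 0 || variability_frac >= 1)
    stop("`variability_frac` must be in [0, 1)")
  if (asymmetry_ratio <= 0) stop("`asymmetry_ratio` must be > 0")
  if (travel_um <= 0) stop("`travel_um` must be > 0")
  structure(
    list(kind = kind, nominal_um_per_unit = nominal_um_per_unit,
         variability_frac = variability_frac,
         asymmetry_ratio = asymmetry_ratio, load_g = load_g,
         travel_um = travel_um, coupling_error_frac = coupling_error_frac,
         settle_amplitude_um = settle_amplitude_um,
         settle_tau_ms = settle_tau_ms, settle_period_ms = settle_period_ms,
         meta = meta),
    class = "actuator_model")
}

#' @export
print.actuator_model <- function(x, ...) {
  cat(sprintf("<actuator_model> %s, %.5f µm/unit, +/-%.0f%%, up/down %.2f, travel %g µm\n",
              x$kind, x$nominal_um_per_unit, 100 * x$variability_frac,
              x$asymmetry_ratio, x$travel_um))
  invisible(x)
}

#' Simulate one actuation command
#'
#' Piezo: a single command of "step size" `|command_units|` produces one
#' displacement drawn from
#' `|units| * mean * (1 + U(-variability_frac, +variability_frac))` — the
#' dispersion applies per actuation, whatever its size, which is why tile
#' moves land up to 20% off and stitching must absorb it. The mean is the
#' nominal calibration for upward (positive) moves and nominal divided by
#' `asymmetry_ratio` for downward moves. Stepper: exactly
#' `units * nominal * (1 + coupling_error_frac)`, deterministic.
#'
#' @param model An [actuator_model()].
#' @param command_units Signed integer command count ("step size").
#' @param seed Integer seed for the piezo draw.
#' @return Signed displacement in µm.
#' @export
actuate <- function(model, command_units, seed = 1L) {
  if (command_units == 0) return(0)
  if (model$kind == "stepper")
    return(command_units * model$nominal_um_per_unit *
             (1 + model$coupling_error_frac))
  dir_up <- command_units > 0
  mean_step <- if (dir_up) model$nominal_um_per_unit else
    model$nominal_um_per_unit / model$asymmetry_ratio
  draw <- with_seed(seed,
    abs(round(command_units)) * mean_step *
      (1 + stats::runif(1, -model$variability_frac, model$variability_frac)))
  sign(command_units) * draw
}

#' Residual post-move oscillation profile
#'
#' Exponentially damped sinusoid describing the stage's residual in-image
#' displacement after a move stops; images are only captured once the
#' envelope has decayed below the acquisition settle threshold.
#'
#' @param model An [actuator_model()].
#' @param t_ms Times since motion stopped, ms (>= 0).
#' @return Signed residual displacement, µm; the decay envelope is attached
#'   as attribute `"envelope"` (also available via [settle_envelope()]).
#' @export
settle_profile <- function(model, t_ms) {
  if (any(t_ms < 0)) stop("`t_ms` must be >= 0")
  env <- settle_envelope(model, t_ms)
  out <- env * cos(2 * pi * t_ms / model$settle_period_ms)
  attr(out, "envelope") <- env
  out
}

#' Oscillation decay envelope
#' @param model An [actuator_model()].
#' @param t_ms Times since motion stopped, ms.
#' @return Envelope amplitude, µm.
#' @export
settle_envelope <- function(model, t_ms) {
  model$settle_amplitude_um * exp(-t_ms / model$settle_tau_ms)
}

#' Virtual multi-axis stage
#'
#' Holds the current position, one actuator model per axis, the per-axis
#' command calibration used to translate distances into command units, and
#' a cumulative command log (one row per issued move).
#'
#' @param actuators Named list of [actuator_model()] per axis; axes `x`,
#'   `y`, `z` required, `a` (approach axis) optional.
#' @param origin Starting position, µm per axis (within travel).
#' @param calibration Optional calibration table (see
#'   [calibration_table()]); defaults to each actuator's true mean
#'   behaviour, i.e. a perfectly calibrated stage.
#' @return An object of class `stage_state`.
#' @export
stage_state <- function(actuators, origin = NULL, calibration = NULL) {
  axes <- names(actuators)
  if (!all(c("x", "y", "z") %in% axes))
    stop("`actuators` must name at least axes x, y, z")
  if (is.null(origin)) origin <- stats::setNames(rep(0, length(axes)), axes)
  origin <- origin[axes]
  for (ax in axes) {
    if (origin[[ax]] < 0 || origin[[ax]] > actuators[[ax]]$travel_um)
      stop(sprintf("origin on axis %s outside [0, %g] µm travel", ax,
                   actuators[[ax]]$travel_um))
  }
  if (is.null(calibration)) calibration <- calibration_table(actuators)
  structure(
    list(actuators = actuators,
         pos = stats::setNames(as.numeric(origin), axes),
         origin = stats::setNames(as.numeric(origin), axes),
         calibration = calibration,
         log = data.frame(move = integer(), axis = character(),
                          units = numeric(), commanded_um = numeric(),
                          achieved_um = numeric(), clamped = logical())),
    class = "stage_state")
}

#' @export
print.stage_state <- function(x, ...) {
  cat("<stage_state> at (",
      paste(sprintf("%s=%.2f", names(x$pos), x$pos), collapse = ", "),
      ") µm, ", nrow(x$log), " moves logged\n", sep = "")
  invisible(x)
}

#' Build a command calibration table from actuator models
#'
#' One row per axis and direction giving the µm-per-unit conversion used to
#' compute command counts. By default the table reflects each model's true
#' mean displacement (nominal for up/positive, nominal / asymmetry for
#' down/negative), i.e. a stage calibrated exactly at its working load;
#' measured calibrations from [calibrate_steps()] can be substituted via
#' [as_calibration_table()].
#'
#' @param actuators Named list of [actuator_model()].
#' @return data.frame with columns axis, direction (`"up"`/`"down"`),
#'   um_per_unit.
#' @export
calibration_table <- function(actuators) {
  do.call(rbind, lapply(names(actuators), function(ax) {
    m <- actuators[[ax]]
    data.frame(axis = ax, direction = c("up", "down"),
               um_per_unit = c(m$nominal_um_per_unit,
                               m$nominal_um_per_unit / m$asymmetry_ratio))
  }))
}

#' Move the stage by a relative distance
#'
#' Issues one open-loop command per axis for the requested displacement —
#' the protocol the scanning loop uses (a serpentine scan sends the same
#' distance command for every tile step, it does not re-target from the
#' achieved position). Commands are computed from the calibration table;
#' the achieved displacement carries the actuator's error. Moves that
#' would pass a travel hard stop are clamped and flagged in the log.
#'
#' @param state A [stage_state()].
#' @param delta Named numeric displacements (subset of axes), µm.
#' @param seed Integer seed for actuation noise.
#' @return Updated `stage_state`.
#' @export
move_by <- function(state, delta, seed = 1L) {
  axes <- intersect(names(state$pos), names(delta))
  if (length(axes) == 0) stop("`delta` names no stage axis")
  seeds <- derive_seeds(seed, length(axes))
  for (k in seq_along(axes)) {
    ax <- axes[k]
    dist <- delta[[ax]]
    if (dist == 0) next
    units <- distance_to_commands(dist, state$calibration, axis = ax)
    disp <- actuate(state$actuators[[ax]], units, seeds[k])
    newpos <- state$pos[[ax]] + disp
    clamped <- FALSE
    if (newpos < 0 || newpos > state$actuators[[ax]]$travel_um) {
      newpos <- min(max(newpos, 0), state$actuators[[ax]]$travel_um)
      disp <- newpos - state$pos[[ax]]
      clamped <- TRUE
    }
    state$log <- rbind(state$log, data.frame(
      move = nrow(state$log) + 1L, axis = ax, units = units,
      commanded_um = dist, achieved_um = disp, clamped = clamped))
    state$pos[[ax]] <- newpos
  }
  state
}

#' Move the stage to a target position
#'
#' Computes per-axis command units from the calibration table (rounding half
#' away from zero), actuates each axis, and returns the updated stage with
#' the true simulated position — which differs from the target for piezo
#' axes. Targets outside the travel range raise an error before any motion;
#' overshoot beyond a hard stop is clamped and flagged in the command log.
#'
#' @param state A [stage_state()].
#' @param target Named numeric target (subset of axes), µm.
#' @param seed Integer seed for actuation noise.
#' @return Updated `stage_state`; achieved position in `$pos`.
#' @export
move_to <- function(state, target, seed = 1L) {
  axes <- intersect(names(state$pos), names(target))
  if (length(axes) == 0) stop("`target` names no stage axis")
  for (ax in axes) {
    if (target[[ax]] < 0 || target[[ax]] > state$actuators[[ax]]$travel_um)
      stop(sprintf("target %s = %g µm is outside the [0, %g] µm travel range",
                   ax, target[[ax]], state$actuators[[ax]]$travel_um))
  }
  seeds <- derive_seeds(seed, length(axes))
  for (k in seq_along(axes)) {
    ax <- axes[k]
    dist <- target[[ax]] - state$pos[[ax]]
    if (dist == 0) next
    units <- distance_to_commands(dist, state$calibration, axis = ax)
    disp <- actuate(state$actuators[[ax]], units, seeds[k])
    newpos <- state$pos[[ax]] + disp
    clamped <- FALSE
    if (newpos < 0 || newpos > state$actuators[[ax]]$travel_um) {
      newpos <- min(max(newpos, 0), state$actuators[[ax]]$travel_um)
      disp <- newpos - state$pos[[ax]]
      clamped <- TRUE
    }
    state$log <- rbind(state$log, data.frame(
      move = nrow(state$log) + 1L, axis = ax, units = units,
      commanded_um = dist, achieved_um = disp, clamped = clamped))
    state$pos[[ax]] <- newpos
  }
  state
}
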