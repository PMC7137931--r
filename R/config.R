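#' Default run configuration
#'
#' The full configuration schema with its default values. Any subset of
#' these keys may appear in a config file; unknown keys are rejected by
#' [load_config()].
#'
#' @return Nested list of configuration blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "stagescan-out",
    optics = list(na = 0.5, wavelength_nm = 530, pixel_um = 0.386,
                  fov_px = 256, defocus_blur_um_per_um = 0.5,
                  vignette_strength = 0.05, photon_scale = 400,
                  read_noise_sd = 0.005, full_scale = 4, bit_depth = 16),
    actuators = list(
      x = list(kind = "piezo", nominal_um_per_unit = 0.05,
               variability_frac = 0.20, asymmetry_ratio = 1.15,
               load_g = 335, travel_um = 13000, coupling_error_frac = 0),
      y = list(kind = "piezo", nominal_um_per_unit = 0.05,
               variability_frac = 0.20, asymmetry_ratio = 1.15,
               load_g = 335, travel_um = 13000, coupling_error_frac = 0),
      z = list(kind = "piezo", nominal_um_per_unit = 0.05,
               variability_frac = 0.20, asymmetry_ratio = 1.15,
               load_g = 335, travel_um = 13000, coupling_error_frac = 0)),
    plan = list(nx = 10L, ny = 5L, overlap_x = 0.25, overlap_y = 0.30,
                origin_x_um = 100, origin_y_um = 100,
                nz = 20L, dz_um = 2, z_start_um = 56),
    specimen = list(extent_x_um = 900, extent_y_um = 500, extent_z_um = 50,
                    n_filaments = 40, pitch_xy_um = 1, pitch_z_um = 2.5,
                    background = 0.05, amplitude = 1,
                    origin_x_um = 0, origin_y_um = 0, origin_z_um = 50),
    acquisition = list(settle_ms = 350, z_correct = TRUE,
                       keep_stacks = FALSE),
    stitching = list(search_radius_px = NA, min_confidence = 0.15,
                     blend_width_px = 16),
    qc = list(mtf_oversample = 4L)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) stop(sprintf("config block '%s' must be a mapping", path))
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0)
    stop(sprintf("unknown config key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(if (nzchar(path)) paste0(path, ".") else "", extra,
                        collapse = ", ")))
  out <- defaults
  for (k in names(user)) {
    sub <- if (nzchar(path)) paste(path, k, sep = ".") else k
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      out[[k]] <- merge_config(defaults[[k]], user[[k]], sub)
    else out[[k]] <- user[[k]]
  }
  out
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop(sprintf("invalid config: %s", msg))
  chk(cfg$optics$na > 0 && cfg$optics$na <= 1, "optics.na must be in (0, 1]")
  chk(cfg$optics$pixel_um > 0, "optics.pixel_um must be > 0")
  chk(cfg$optics$vignette_strength >= 0 && cfg$optics$vignette_strength <= 1,
      "optics.vignette_strength must be in [0, 1]")
  chk(cfg$plan$overlap_x >= 0 && cfg$plan$overlap_x < 1,
      "plan.overlap_x must be in [0, 1)")
  chk(cfg$plan$overlap_y >= 0 && cfg$plan$overlap_y < 1,
      "plan.overlap_y must be in [0, 1)")
  chk(cfg$plan$nx >= 1 && cfg$plan$ny >= 1, "plan.nx/ny must be >= 1")
  chk(cfg$plan$nz >= 1, "plan.nz must be >= 1")
  for (ax in names(cfg$actuators)) {
    a <- cfg$actuators[[ax]]
    chk(a$kind %in% c("piezo", "stepper"),
        sprintf("actuators.%s.kind must be piezo or stepper", ax))
    chk(a$nominal_um_per_unit > 0,
        sprintf("actuators.%s.nominal_um_per_unit must be > 0", ax))
    chk(a$variability_frac >= 0 && a$variability_frac < 1,
        sprintf("actuators.%s.variability_frac must be in [0, 1)", ax))
  }
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a JSON (`.json`) or YAML (`.yaml`/`.yml`) configuration file,
#' fills unset keys from [default_config()], rejects unknown keys by name,
#' validates the invariants, and records a deterministic hash of the
#' resolved configuration.
#'
#' @param path Config file path.
#' @return An object of class `run_config` (the resolved configuration,
#'   with the hash in `$config_hash`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported config format '.%s' (use .json or .yaml)", ext)))
  cfg <- merge_config(default_config(), user %||% list())
  validate_config(cfg)
  cfg$config_hash <- hash_object(cfg)
  structure(cfg, class = "run_config")
}

#' Build the simulator objects described by a configuration
#'
#' @param cfg A [load_config()] result (or [default_config()] output).
#' @return List: `optics` ([optics_model()]), `stage` ([stage_state()]),
#'   `plan` ([plan_serpentine()]), `specimen` ([make_nervenet_specimen()]
#'   output; generated with the config seed).
#' @export
config_objects <- function(cfg) {
  o <- cfg$optics
  optics <- optics_model(na = o$na, wavelength_nm = o$wavelength_nm,
                         pixel_um = o$pixel_um, fov_px = o$fov_px,
                         defocus_blur_um_per_um = o$defocus_blur_um_per_um,
                         vignette_strength = o$vignette_strength,
                         photon_scale = o$photon_scale,
                         read_noise_sd = o$read_noise_sd,
                         full_scale = o$full_scale, bit_depth = o$bit_depth)
  actuators <- lapply(cfg$actuators, function(a)
    actuator_model(kind = a$kind, nominal_um_per_unit = a$nominal_um_per_unit,
                   variability_frac = a$variability_frac,
                   asymmetry_ratio = a$asymmetry_ratio, load_g = a$load_g,
                   travel_um = a$travel_um,
                   coupling_error_frac = a$coupling_error_frac))
  p <- cfg$plan
  fov_um <- o$fov_px * o$pixel_um
  plan <- plan_serpentine(p$nx, p$ny, fov_um, p$overlap_x, p$overlap_y,
                          origin = c(p$origin_x_um, p$origin_y_um),
                          nz = p$nz, dz_um = p$dz_um, z_start = p$z_start_um)
  s <- cfg$specimen
  specimen <- make_nervenet_specimen(
    c(s$extent_x_um, s$extent_y_um, s$extent_z_um), s$n_filaments,
    seed = cfg$seed, pitch_xy = s$pitch_xy_um, pitch_z = s$pitch_z_um,
    background = s$background, amplitude = s$amplitude,
    origin_um = c(s$origin_x_um, s$origin_y_um, s$origin_z_um))
  stage <- stage_state(actuators,
                       origin = c(x = p$origin_x_um, y = p$origin_y_um,
                                  z = p$z_start_um))
  list(optics = optics, stage = stage, plan = plan, specimen = specimen)
}
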