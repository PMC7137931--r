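test_that("chart resolution follows the sixth-octave doubling rule", {
  expect_equal(res_lp(2, 4), 2^2.5, tolerance = 1e-12)
  expect_equal(res_lp(0, 1), 1)
  # strictly increasing through (group, element) order, -2..7 x 1..6
  seqs <- unlist(lapply(-2:7, function(g) res_lp(g, 1:6)))
  expect_true(all(diff(seqs) > 0))
  # element steps multiply by 2^(1/6); group steps by 2
  expect_equal(res_lp(3, 2) / res_lp(3, 1), 2^(1 / 6))
  expect_equal(res_lp(4, 1) / res_lp(3, 1), 2)
  expect_error(res_lp(3, 0), "1..6")
  expect_error(res_lp(3, 7), "1..6")
})

test_that("line-pair spacing inverts the resolution", {
  expect_equal(res_cc(1), 1000)
  expect_equal(res_cc(res_lp(7, 6)), 4.385, tolerance = 1e-3)
  # spacing strictly decreases as elements get finer
  sp <- res_cc(unlist(lapply(-2:7, function(g) res_lp(g, 1:6))))
  expect_true(all(diff(sp) < 0))
  expect_error(res_cc(0), "> 0")
})

test_that("diffraction limits follow the Abbe and Rayleigh formulas", {
  expect_equal(abbe_limit(530, 0.5), 530)       # equals the wavelength at NA 0.5
  expect_equal(abbe_limit(700, 1.0), 350)       # lambda / 2 at NA 1
  expect_equal(rayleigh_limit(530, 0.5), 646.6)
  expect_equal(round(rayleigh_limit(530, 0.5)), 647)
  expect_error(abbe_limit(530, 0), "> 0")
})

test_that("illumination uniformity reports ratio 1 and CV 0 on flat fields", {
  rep1 <- illumination_uniformity(matrix(5, 64, 64))
  expect_equal(rep1$corner_centre_ratio, 1, tolerance = 1e-9)
  expect_equal(rep1$cv, 0, tolerance = 1e-9)
})

test_that("a 10% synthetic corner vignette is measured and scale-invariant", {
  field <- stagescan:::vignette_field(96, 0.10)
  rep1 <- illumination_uniformity(field)
  expect_equal(rep1$corner_centre_ratio, 0.90, tolerance = 0.01)
  rep2 <- illumination_uniformity(field * 1234)
  expect_equal(rep2$corner_centre_ratio, rep1$corner_centre_ratio,
               tolerance = 1e-9)
  expect_equal(rep2$cv, rep1$cv, tolerance = 1e-9)
})

test_that("calibration statistics summarize grouped step measurements", {
  m <- data.frame(axis = "z", direction = "up",
                  step_size = rep(c(20, 50), each = 3),
                  distance_um = c(1.0, 1.1, 0.9, 2.4, 2.6, 2.5))
  cal <- calibrate_steps(m)
  r <- cal$records
  expect_equal(r$n, c(3, 3))
  expect_equal(r$mean_um, c(1.0, 2.5))
  expect_equal(r$sd_um[1], sd(c(1.0, 1.1, 0.9)))
  # through-origin slope: sum(xy) / sum(x^2)
  x <- m$step_size; y <- m$distance_um
  expect_equal(cal$slopes$um_per_unit, sum(x * y) / sum(x^2))
})

test_that("a single measurement reports a mean but no SD", {
  m <- data.frame(axis = "z", direction = "down", step_size = 20,
                  distance_um = 1.05)
  cal <- calibrate_steps(m)
  expect_equal(cal$records$mean_um, 1.05)
  expect_true(is.na(cal$records$sd_um))
})

test_that("simulated calibration recovers actuator parameters within 2 SE", {
  pz <- actuator_model("piezo", nominal_um_per_unit = 0.05)
  m <- simulate_step_measurements(pz, n_repeats = 15, seed = 21)
  expect_equal(nrow(m), 2 * 5 * 15)
  cal <- calibrate_steps(m)
  up <- cal$slopes[cal$slopes$direction == "up", ]
  dn <- cal$slopes[cal$slopes$direction == "down", ]
  expect_lt(abs(up$um_per_unit - 0.05), 2 * up$se)
  expect_lt(abs(dn$um_per_unit - 0.05 / pz$asymmetry_ratio), 2 * dn$se)
  # asymmetric model: up means exceed down means per step size
  per <- merge(cal$records[cal$records$direction == "up", ],
               cal$records[cal$records$direction == "down", ],
               by = "step_size")
  expect_true(all(per$mean_um.x > per$mean_um.y))
})

test_that("measured calibrations can drive the stage", {
  pz <- actuator_model("piezo")
  cal <- calibrate_steps(simulate_step_measurements(pz, n_repeats = 15,
                                                    axis = "z", seed = 3))
  tab <- as_calibration_table(cal)
  expect_named(tab, c("axis", "direction", "um_per_unit"))
  units <- distance_to_commands(10, tab, "z")
  expect_equal(units * tab$um_per_unit[tab$direction == "up"], 10,
               tolerance = 0.5)
})
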