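test_that("stepper gearing converts microsteps to exact displacements", {
  st <- actuator_model("stepper")
  expect_identical(actuate(st, 16), 2.5)       # one full step of the 500 µm/rev micrometer
  expect_identical(actuate(st, 1), 0.15625)    # one 1/16 microstep
  expect_identical(actuate(st, -16), -2.5)
  expect_identical(actuate(st, 0), 0)
})

test_that("piezo displacement stays within the 20% dispersion bound", {
  pz <- actuator_model("piezo")
  n <- 1000
  ups <- vapply(seq_len(n), function(i) actuate(pz, 1, seed = i), numeric(1))
  devs <- abs(ups - pz$nominal_um_per_unit) / pz$nominal_um_per_unit
  expect_lte(max(devs), 0.20)
  expect_gt(max(devs), 0.10)   # the bound is actually exercised
  expect_identical(actuate(pz, 0, seed = 1), 0)
})

test_that("piezo up-travel exceeds down-travel under the default asymmetry", {
  pz <- actuator_model("piezo")
  ups <- vapply(1:200, function(i) actuate(pz, 100, seed = i), numeric(1))
  downs <- vapply(1:200, function(i) abs(actuate(pz, -100, seed = 1000 + i)),
                  numeric(1))
  expect_gt(mean(ups), mean(downs))
  expect_equal(mean(ups) / mean(downs), pz$asymmetry_ratio, tolerance = 0.05)
})

test_that("move_to reaches targets within quantization (stepper) or dispersion (piezo)", {
  st <- ideal_stepper_stage()
  st <- move_to(st, c(x = 100, y = 200, z = 50), seed = 1)
  expect_lt(max(abs(st$pos[c("x", "y", "z")] - c(100, 200, 50))), 0.157)

  pz <- default_piezo_stage(origin = c(x = 0, y = 0, z = 0))
  pz <- move_to(pz, c(x = 100, y = 200, z = 50), seed = 2)
  for (ax in c("x", "y", "z")) {
    target <- c(x = 100, y = 200, z = 50)[[ax]]
    expect_lt(abs(pz$pos[[ax]] - target) / target, 0.201)
  }
})

test_that("targets beyond the 13 mm travel error out before any motion", {
  st <- ideal_stepper_stage(origin = c(x = 10, y = 10, z = 10))
  expect_error(move_to(st, c(x = 14000), seed = 1), "travel")
  expect_equal(st$pos[["x"]], 10)   # unchanged
  expect_equal(nrow(st$log), 0)
})

test_that("overshoot past a hard stop is clamped and flagged in the log", {
  pz <- stage_state(list(x = actuator_model("piezo"), y = actuator_model("piezo"),
                         z = actuator_model("piezo")),
                    origin = c(x = 12990, y = 0, z = 0))
  # relative move whose piezo draw can exceed the remaining 10 µm
  pz2 <- move_by(pz, c(x = 10.5), seed = 3)
  expect_lte(pz2$pos[["x"]], 13000)
  if (pz2$pos[["x"]] == 13000) expect_true(any(pz2$log$clamped))
})

test_that("logged displacements conserve the net position change", {
  pz <- default_piezo_stage(origin = c(x = 100, y = 100, z = 100))
  set <- list(c(x = 140), c(y = 60), c(x = 90, z = 180), c(y = 220, z = 40))
  for (i in seq_along(set)) pz <- move_to(pz, set[[i]], seed = i)
  for (ax in c("x", "y", "z")) {
    logged <- sum(pz$log$achieved_um[pz$log$axis == ax])
    expect_equal(logged, pz$pos[[ax]] - pz$origin[[ax]], tolerance = 1e-9)
  }
})

test_that("identical stepper command sequences reproduce identical positions", {
  run <- function() {
    st <- ideal_stepper_stage()
    st <- move_by(st, c(x = 123.4, y = 77.7), seed = 1)
    st <- move_by(st, c(x = -55.1, z = 10), seed = 2)
    st$pos
  }
  expect_identical(run(), run())
})

test_that("settle profile decays from its initial amplitude", {
  m <- actuator_model("stepper", settle_amplitude_um = 0.8, settle_tau_ms = 50,
                      settle_period_ms = 20)
  expect_equal(as.numeric(settle_profile(m, 0)), 0.8)
  expect_lt(abs(settle_profile(m, 2000)), 1e-9)
  # envelope at 5 time-constants is under 1% of the initial amplitude
  expect_lt(settle_envelope(m, 5 * 50), 0.01 * 0.8)
  expect_error(settle_profile(m, -1), ">= 0")
})
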