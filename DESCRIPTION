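Package: stagescan
Title: Virtual Automated Microscope Stage Scanning, Stitching and Optical QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation and analysis stack for automated microscope stage
    scanning. Provides a virtual microscope (synthetic fluorescent specimens,
    a parametric camera/optics model, and motion models for piezoelectric
    inertial actuators and micrometer-coupled stepper motors), serpentine
    tile planning with Z-stacks and a gcode emitter, autofocus-scored
    acquisition with inter-tile Z-correction and maximum intensity
    projection, phase-correlation tile stitching with global position
    refinement, and optical quality-control mathematics (USAF 1951
    resolution formulas, Abbe and Rayleigh diffraction limits, slant-edge
    MTF estimation, drift tracking, and actuator step-size calibration
    statistics). Every procedure is testable end-to-end against the
    simulator without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
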