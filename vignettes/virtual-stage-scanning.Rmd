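---
title: "Virtual automated stage scanning: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual automated stage scanning: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagescan)
```

stagescan simulates and analyses the computational side of an automated
fluorescence-microscope scanning stage: serpentine tile acquisition with
Z-stacks, autofocus-driven Z-correction, maximum intensity projection,
phase-correlation stitching, and the optical quality-control mathematics
(USAF 1951 resolution, diffraction limits, slant-edge MTF, drift, actuator
calibration). The virtual microscope — a synthetic specimen, an optics
model, and parametric actuator models — makes every procedure testable end
to end without hardware. This vignette documents the models, the tunable
parameters, the numerical choices, and what the simulations do and do not
demonstrate about a physical instrument.

## The virtual specimen

`make_nervenet_specimen()` emulates a whole-mount epithelial nerve net of a
gelatinous marine invertebrate: a polygonal mesh of thin fluorescent
filaments (Gaussian cross-section, default sigma 1.5 µm) with brighter
cell-body puncta at the mesh nodes, draped over a smoothly undulating
height surface. The surface matters: it makes the in-focus plane vary
across XY, which is precisely why the scanning procedure needs Z-stacks and
inter-tile Z-correction. Defaults: background 0.05, filament amplitude up
to 1 (arbitrary fluorescence units), surface amplitude 25% of the Z extent,
voxel pitch 1 µm in XY and 2.5 µm in Z. The generator is deterministic for
a fixed seed.

What it does *not* emulate: photobleaching, scattering, depth-dependent
attenuation, multi-channel labels, or oblique-illumination shading. Passing
tests on this specimen demonstrate the correctness of the acquisition and
analysis logic under a realistic geometry — not robustness to every optical
artefact of real tissue.

## The camera model

`render_frame()` forms an image as a sum of volume planes, each blurred by
a Gaussian whose sigma grows linearly with its distance from the focal
plane (`defocus_blur_um_per_um`, default 0.5 µm of sigma per µm of
defocus). This is deliberately not a diffraction PSF: the procedures under
test (focus scoring, MIP, registration) depend on blur growing monotonically
with defocus, not on its exact shape, and the Gaussian admits closed-form
oracles. Vignetting is a radial cosine-fourth-style falloff with the corner
at `1 - vignette_strength` of the centre (default 5%, i.e. nearly uniform
illumination). Noise is Poisson photon noise (default scaling gives
signal-to-noise of about 20 on unit-intensity structures) plus Gaussian read
noise, then quantization to 16 bits.

Numerically, rendering works in the Fourier domain: each volume plane in a
padded window around the field of view is transformed once per tile, each
frame multiplies the cached spectra by the Gaussian transfer function and
performs one inverse FFT. Pad sizes are rounded up to 7-smooth FFT lengths.
Planes defocused so far that their blur sigma exceeds 30 px are folded in
as their mean intensity — at that blur a plane is constant to well below
one grey level across a frame, and the shortcut is what keeps a 1000-frame
scan in the minutes range on one CPU. The circular-convolution wrap-around
is confined to the pad margin (at least three sigma of the largest kernel
actually convolved).

Conventions, used everywhere: physical units µm; images are `[row, col]`
matrices with row 1 at minimum Y; a stage position `c(x, y, z)` puts the
frame's minimum-X/minimum-Y corner at `(x, y)` and the focal plane at depth
`z` (larger z focuses deeper); all axes travel 0–13 000 µm.

## The motion models

Two actuator families (`actuator_model()`):

* **Piezoelectric inertial actuators** are open loop. One command of "step
  size" `s` produces a single displacement draw
  `s × nominal × (1 + U(−v, +v))` with `v = 0.20` by default — the
  dispersion applies per actuation, whatever its size. The distribution is
  uniform because only the ±20% bound is characterized for the physical
  device; truncation makes the bound exact. Downward moves travel less than
  upward ones by `asymmetry_ratio` (default 1.15 — the reference
  observation is qualitative, so the ratio is configurable). The µm value
  of one command unit is a per-configuration calibrated constant (default
  0.05 µm/unit at the reference 335 g load); it is load-dependent on the
  real device and the package treats measured calibration tables, not a
  universal constant, as its source.
* **Micrometer-coupled steppers** are deterministic: 500 µm per revolution
  and 200 steps per revolution give exactly 2.5 µm per full step and
  156.25 nm per 1/16 microstep. A configurable `coupling_error_frac`
  (default 0) can mimic the fixed scale error of an imperfect 3D-printed
  coupling.

`move_by()` issues open-loop relative commands — the scanning protocol —
while `move_to()` is a closed-loop convenience for set-up moves. The
distinction matters: a serpentine scan sends the same pitch command for
every tile step, so adjacent tiles disagree by at most one move's error
(±20% of the pitch), while absolute re-targeting would compound two moves'
errors into one tile seam. Post-move residual oscillation is modelled as an
exponentially damped sinusoid (`settle_profile()`); frames are captured
only after the settle window, never during motion.

## Scanning, Z-correction, projection

`plan_serpentine()` builds the boustrophedon grid; overlap is defined as
the shared fraction of the field of view, `pitch = fov × (1 − overlap)`,
which reproduces the reference 25% (X) / 30% (Y) piezo settings and the
10% stepper setting directly. The first row scans in +X. `to_gcode()`
emits an absolute-positioning millimetre program (G21/G90 preamble, one G1
move per tile, 4 decimals = 0.1 µm round trip) for the stepper stage.

Each tile acquires `nz` frames at `dz_um` spacing, scores each with the
focus metric, and records the per-pixel maximum as the MIP. The autofocus
metric is mean squared Sobel gradient magnitude (Tenengrad family). It is
not normalized by the mean intensity: the plain form is exactly invariant
to additive offsets, which the contract requires, whereas mean
normalization would trade that for scale invariance the pipeline does not
need. The metric is a plug-in argument to `run_scan()`, so alternatives
can be swapped without touching the loop. Ties in the best-focus index
break toward the lower plane.

Z-correction re-centres the previous tile's best-focus plane:
`offset = (best − (nz + 1) / 2) × dz` with 1-based indices, accumulated
across tiles and applied to the stack-return move. Whether the physical
procedure re-centres on the stack middle or the first in-focus plane is not
documented; middle-centring is symmetric and keeps maximal headroom both
ways, so that is what is implemented. Corrections are cumulative because
the two drivers of defocus drift — specimen slope and the piezo's up/down
travel asymmetry (the stack climbs up, the return travels down) — are both
cumulative. A featureless tile (all focus scores zero) leaves the carried
correction unchanged and logs a warning.

## Stitching

Pairwise neighbour offsets are estimated in a window around the plan's
nominal offset (the crops are the predicted overlap expanded by the search
radius, zero-padded beyond image borders) by phase correlation with a Hann
window and sub-pixel quadratic refinement. Two robustness layers were
necessary and are fixed parts of the recipe:

* The normalized cross-power spectrum is weighted by a Gaussian low-pass
  (sigma 2 px in the spatial domain). Plain phase correlation weights all
  frequencies equally, and on noisy fluorescence the noise-dominated band
  drowns the true peak.
* The top five phase peaks are *verified*: each candidate's implied overlap
  is compared by normalized cross-correlation of high-passed crops (local
  mean removed by mask-aware normalized convolution, so background,
  vignetting and pad borders cannot vote), the best candidate wins, is
  refined by hill-climbing the NCC surface, and its NCC becomes the edge
  confidence. Unverified phase peaks are ambiguous on sparse, self-similar
  mesh content; verification is what makes 25–30% overlaps reliable.

Global placement solves a weighted least-squares problem over the edge
graph (tile 1 anchored at the origin, weights = confidence squared),
refined by iteratively-reweighted least squares with a Cauchy loss whose
scale tracks the consensus spread, plus leave-out trials on the worst few
edges scored by the robust cost — the squared-error optimum can sit in a
basin where a single corrupted edge drags the whole grid relative to the
anchor, and the trials escape it. A grid has row and column redundancy, so
a corrupted or featureless edge is voted down. Composition uses
linear feathering over `blend_width_px` (default 16); with width 0 the
mosaic is hard-edged and the last tile written wins. No multiband
blending, rotation, or illumination harmonization: MIP fluorescence tiles
from one detector do not need them, and the simpler blend is exactly
testable (a cut-up image must reassemble to within one grey level).

## Optical QC

* `res_lp(g, e) = 2^(g + (e − 1)/6)` lp/mm and `res_cc = 1000 / res_lp` µm
  are exact closed forms. Note that at group 7 element 6 these give
  228 lp/mm and a 4.39 µm line-pair period (2.19 µm line width); a
  sometimes-quoted "1.1 µm" for that element is not consistent with the
  chart formulas, and the package reports the formula values.
* `abbe_limit() = λ/2NA`; `rayleigh_limit()` is 1.22× that (646.6 nm at
  530 nm and NA 0.5, conventionally rounded to 647 nm).
* `slant_edge_mtf()` follows the ISO 12233-style pipeline: per-row gradient
  centroids regressed for the edge angle (2–15° accepted), projection onto
  the edge normal, binning into an oversampled edge-spread function (4×
  default; empty bins interpolated), finite-difference differentiation to
  the line-spread function, Hamming window centred on the LSF peak, DFT
  magnitude, normalization to 1 at zero frequency. The finite-difference
  derivative attenuates by `sinc(f Δ)` (Δ = one oversampled bin); the
  estimate divides that out. Against the closed-form oracle — an area-
  sampled edge with optional exact Gaussian blur, whose true MTF is
  `exp(−2π²σ²f²)·|sinc(f)|` — the estimator is accurate to well under 1%
  up to the Nyquist frequency; the tests assert 2% (unblurred) and 3%
  (blurred) bounds.
* `calibrate_steps()` reduces repeated displacement measurements to
  per-step-size means and SDs (SD only for n ≥ 2, matching the convention
  that unresolvable repeats report a mean only) and fits µm-per-unit by
  least squares through the origin — zero command producing zero
  displacement is physical, so the intercept is not estimated. Parameter
  recovery is verified on simulated actuators at the reference protocol
  (step sizes 1000/500/250/50/20, n = 15 per direction).
* `measure_displacement()` and `drift_track()` automate the video-based
  distance measurements with the same registration engine as stitching.

## Study conditions used by the tests

The acceptance-style checks run at fixed problem sizes chosen to represent
the reference workflow on one CPU: the bookkeeping scan is the full 10×5
grid with 20-plane stacks at 256² px tiles over a 900×500×50 µm specimen;
the end-to-end stitching demonstration uses a 5×4 piezo scan at 384² px
tiles (closer to the physical camera's field) over an 800×650 µm specimen
with 500 filament segments and a gentle (5 µm) surface undulation fully
covered by the 10-plane stacks, so that the claim under test — that 25/30%
overlap absorbs ±20% XY step error — is isolated from Z-coverage failures,
which are exercised separately by the tilted-specimen Z-correction test.
Piezo dispersion bounds are checked over at least 1000 independent draws.

## Configuration and reproducibility

Configs are JSON or YAML (`load_config()`): YAML keeps human-edited
experiment files commentable, and both formats map onto one validated
schema with defaults, unknown-key rejection, and an MD5 hash of the
canonical serialization recorded in every manifest. One global seed is
expanded into per-tile and per-frame child seeds by drawing from a stream
seeded with the master (`derive_seeds()`), so any tile can be re-rendered
in isolation. Scan manifests record plan, seeds, achieved positions,
focus scores, corrections and the config hash — enough to re-run a scan
exactly; a mid-scan failure still writes the manifest with the completed
tiles and a failure marker.

## Known limitations

* The optics are geometric-Gaussian; no diffraction PSF, no chromatic or
  spectral model. MTF estimates of *rendered* scenes therefore reflect the
  model, not physical optics.
* Timing-domain behaviour (stage speed, settle milliseconds) is modelled
  only qualitatively by the damped-oscillation profile; no electrical or
  thermal model of the drivers.
* Stitching assumes pure translation between tiles — no rotation,
  deformation, or per-tile intensity correction.
* The piezo error model is independent uniform noise per actuation; real
  devices also show load- and history-dependent systematics that only a
  measured calibration table can capture.
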