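---
title: "Methods: scanner-based DPPH quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanner-based DPPH quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The assay and the two read-outs

DPPH (2,2-diphenyl-1-picrylhydrazyl) is a stable purple radical with a
strong absorption near 517 nm. An antioxidant reduces it to a pale yellow
product, so the degree of scavenging can be read either from the absorbance
drop in a cuvette or — the point of this package — from the colour of a
reaction-mixture drop dried onto a white TLC plate and scanned.

The two potency summaries are:

* **SC50** (spectrophotometric): the antioxidant concentration at which the
  absorbance falls to half its initial value `A0` (the reagent blank).
* **CSC50** (colorimetric): the concentration at which the spot's *colour
  value* — the mean grey level inside a circular region of interest — rises
  halfway from the zero-scavenging reference (the dark, fully radical spot)
  to its value at complete DPPH reduction.

Both are read off dose–response curves built over a serial-dilution ladder
(typically two-fold, "1:1", e.g. nine levels from 3000 µM), each level
dropped in triplicate. CSC50 can be located two ways: at the half-rise of
the colour-value curve (*half-maximum method*) or at the maximum of
Δ(colour value)/Δ(concentration) (*first-derivative method*, the steepest
point of the curve). For a symmetric sigmoid the two coincide.

## Image quantification

* **Greyscale.** RGB scans are collapsed with the luminance weights
  0.299/0.587/0.114 and rounded *half-up* to integer greys; the mean grey
  value then averages those stored integers, matching what desktop image
  software reports. Whether the original workflow used weighted luminance or
  a plain channel average is not documented anywhere we know of; weighted
  luminance (the ImageJ-style default) is this package's declared choice.
* **ROI rule.** A pixel belongs to a spot's ROI iff its centre lies within
  `spot_radius` of the spot centre — no partial-pixel weighting — so
  `n_pixels` is a reproducible integer and the measured mean is exactly a
  finite average. The ROI shape/size of the original workflow is likewise
  undocumented; a circle of the layout radius is our choice.
* **Centre refinement.** Scans never land spots exactly on the nominal
  grid. Within a window of half-width `spot_radius + search_radius` (capped
  below half the pitch) around each nominal centre, the background is
  estimated as the 90th percentile of window greys; pixels whose dark
  deviation is at least half the maximal deviation are averaged, weighted by
  deviation. The displacement is clamped to `search_radius`; windows with
  maximal deviation below `min_contrast` (default 2 grey levels, i.e.
  indistinguishable from quantisation) fall back to the nominal centre and
  are flagged. Refinement assumes spots darker than their local background —
  the polarity of a DPPH drop on a pale plate; nearly fully scavenged spots
  legitimately fall back.
* **Formats.** PNG round-trips 8-bit rasters exactly and is what the test
  suite uses; JPEG is accepted with a widened tolerance (±2 grey levels)
  because its compression is lossy. TIFF is not supported in this build: no
  TIFF codec is available in the dependency set, and adding a hand-rolled
  reader would be worse than an honest error.

## Curve construction and estimators

Replicates are aggregated per concentration into mean, sample standard
deviation (n − 1; 0 when n = 1) and n; estimators see the *mean* curve and
replicate scatter surfaces through the sd column and the validation module.

Interpolation is linear on the *linear* concentration axis, between the
first adjacent pair of means bracketing the target when scanning from the
lowest concentration — the numeric equivalent of reading the printed graph.
An exact hit returns that concentration without interpolation. If the
target lies outside the observed response range the result is censored
(`censored_low`/`censored_high`) with no value rather than an
extrapolation. Non-monotone mean curves are not an error: the first
crossing is used and the result carries `non_monotone_warning`.

The derivative method uses raw forward differences assigned to the
arithmetic midpoint of each concentration pair, no smoothing (a moving-
average hook exists, default off, because any smoother adds parameters the
graphical procedure never states). The maximum-slope midpoint is the
estimate; ties break toward the lowest concentration and carry
`tie_warning`. Midpoint assignment (rather than an endpoint) is our
documented choice; on a two-fold ladder it places the estimate half an
interval below the upper bracketing level, which is why the derivative
CSC50 sits systematically below the half-max CSC50 on coarse geometric
ladders while the two agree within one grid step on dense uniform grids.

`max_response` defaults to the largest observed mean when the complete-
reduction plateau is not supplied; this biases CSC50 low if the plateau is
unreached, so the condition is flagged in the result diagnostics.

Coloured extracts darken their spots without any DPPH; the correction is
additive: corrected = response − (extract-blank − clean-plate baseline),
applied per level or with one pooled blank. How blank results enter the
original graph construction is not specified; the additive model is the
simplest one consistent with blanks measured as separate drops.

## Validation metrics

No LOD/LOQ formula is stated in the assay literature this package follows,
so the ICH-style blank-noise convention is adopted and documented as an
assumption: LOD = 3.3 σ/S, LOQ = 10 σ/S, with σ the sample sd of replicate
blank responses and S the OLS slope of mean response over the lowest
`n_low_levels` (default 3) concentrations, taken in magnitude so decreasing
absorbance calibrations work. LOQ/LOD ≡ 10/3.3 by construction. CV is the
per-level replicate CV averaged across levels (per-level values are also
obtainable); whether the original CV was per-level, pooled or at one
reference concentration is unstated. Cross-method agreement is OLS of CSC50
on SC50 with R² = 1 − SSres/SStot — matching how such comparisons are
plotted — not a concordance coefficient; Bland–Altman is out of scope.

## The simulator: a stated world

The generator exists so every pipeline stage can be tested against known
ground truth; its defaults are fixed once and are not tuning knobs.

* **Chemistry stand-in.** The scavenged fraction is logistic: by default a
  Hill curve `f(c) = c^h/(c^h + c50^h)` (logistic in log-concentration,
  `f(0) = 0`, `f(c50) = ½` exactly) with `h = 2`, a typical steepness for
  antioxidant dose–response data; a linear-axis logistic with rate
  `4h/c50` is available for symmetric-curve tests. The real assay implies no
  functional form — it reads graphs — so this is a declared simulation
  choice, not a claim about chemistry.
* **Absorbance branch.** `A(c) = a0 (1 − f(c)) + ε`, truncated at 0, with
  `a0 = 0.9` — a typical 517 nm reading of the diluted working solution in
  a 1 cm cuvette.
* **Plate branch.** Spot interior grey = `background − depth·(1 − f(c))`;
  defaults background 200, depth 140, so an unscavenged spot reads ≈ 60 on
  a pale plate, visually similar to published spot images. Edges are
  raised-cosine over ±2 px so partial-volume rim pixels exercise the ROI
  mean. The scanner is an affine transform `g' = gain·(g − 128) + 128 +
  offset` (then clipping); defaults are the identity because vendor
  brightness/contrast scales (e.g. "−100 / 85") are not calibrated gains —
  the transform models the *kind* of acquisition distortion, and tests
  verify it is applied before noise (scanner-referred signal, sensor-
  dominated noise; switchable). Per-pixel Gaussian noise defaults to
  sd = 2 grey levels, a moderate flatbed-scanner noise floor.
* **Ground truth** is each spot's mean over its ROI disc of the noiseless,
  scan-transformed, quantised image — exactly what an ideal quantifier
  should recover, making the round-trip tolerance (±0.5 grey) purely a
  quantisation bound.
* **What a green test does not establish.** The simulator has no
  chromatographic diffusion, drying rings, illumination gradients, plate
  texture, or colour chemistry; real scans will be noisier and structured.
  Recovery results bound algorithmic error, not laboratory error.

## Numerical choices and degenerate inputs

Seeds fully determine simulations (bit-identical images and tables; the
caller's RNG state is saved and restored). Units are opaque labels,
enforced uniform within a sample at every boundary. CSV artefacts are
comma-separated UTF-8 with "." decimals and mandatory headers; missing
values are empty fields. Outputs are never silently overwritten without
`force`. Degenerate requests fail with classed errors (overlapping ROIs,
out-of-bounds ROI naming the well, `max_response ≤ blank`, fewer than two
concentrations, fewer than three agreement pairs, zero-variance regressors).

## Known limitations

Only PNG/JPEG input; circular ROIs on a regular grid (no free-form blob
detection); no parametric 4PL/Hill fitting of measured curves — the
estimators deliberately mirror graphical read-off; no kinetic modelling of
the incubation time course; refinement assumes dark spots on a pale
background.
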