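# dpphplate

Spectrophotometer-free quantification of the DPPH radical-scavenging
antioxidant assay from scanned plate images.

DPPH (2,2-diphenyl-1-picrylhydrazyl) is a stable purple radical;
antioxidants bleach it to pale yellow. The classical read-out measures the
absorbance drop at 517 nm and reports **SC50**, the concentration halving
the initial absorbance A0. The scanner-based alternative drops the
incubated reaction mixtures onto a white TLC plate, scans it, and measures
each spot's *colour value* — the mean grey level inside a circular ROI.
The colorimetric potency is **CSC50**, the concentration raising the colour
value halfway from the zero-scavenging reference (dark, fully radical spot)
to its value at complete DPPH reduction. Both are read off serial-dilution
dose–response curves by linear interpolation; CSC50 can also be located at
the maximum of Δ(colour value)/Δ(concentration), the curve's steepest point
(first-derivative method).

The package is aimed at assay developers and screening labs that want the
plate branch of this workflow to be reproducible code rather than manual
image-software clicks: grid layouts, ROI densitometry with centre
refinement, both half-max estimators, assay-validation metrics
(LOD = 3.3 σ/S, LOQ = 10 σ/S, CV, OLS cross-method R²), and a seeded
simulator that renders plates with known ground truth so every stage is
testable without wet-lab data.

## Worked example

Simulate a plate for one analyte with true half-scavenging concentration
200 µM (nine-level two-fold ladder from 3200 µM, triplicates, three reagent
blanks), quantify the rendered scan, and fit CSC50 both ways:

```r
library(dpphplate)
cfg <- default_sim_config(true_c50 = 200, seed = 7)
jsonlite::write_json(cfg, "sim.json", auto_unbox = TRUE, digits = NA)

run_pipeline(list(subcommand = "simulate", config_path = "sim.json", out_dir = "demo"))
run_pipeline(list(subcommand = "quantify", image = "demo/plate.png",
                  layout = "demo/layout.json", out = "demo/spots.csv"))
run_pipeline(list(subcommand = "fit", measurements = "demo/spots.csv",
                  kind = "colour", out = "demo/results.csv"))
read_results_csv("demo/results.csv")
#>   sample_id           method    value unit status
#> 1   analyte    csc50_halfmax 198.9892   uM     ok
#> 2   analyte csc50_derivative 150.0000   uM     ok
```

The half-maximum estimate recovers the true 200 µM to 0.5 % despite 2 grey
levels of per-pixel scanner noise. The derivative estimate is 150 µM: on a
two-fold ladder the steepest-interval midpoint sits half an interval below
the upper bracketing level (here the 100–200 µM interval), a known
granularity of the derivative method on geometric ladders — on dense
uniform grids the two estimators agree within one grid step.

The same machinery drives a full method comparison across both assay
branches:

```r
rec <- end_to_end_recovery(c(20, 63, 200, 632, 2000), seed = 1)
rec
#> <recovery_report> 5 analyte(s)
#>    sample_id true_c50 sc50 csc50_halfmax csc50_derivative
#> 1 analyte_01       20   20      19.94999            15.00
#> 2 analyte_02       63   63      62.74773            47.25
#> 3 analyte_03      200  200     198.95109           150.00
#> 4 analyte_04      632  632     629.94504           474.00
#> 5 analyte_05     2000 2000    1995.57069          1500.00
#>   half-max  agreement R^2 = 1.0000
#>   derivative agreement R^2 = 1.0000
```

`sc50` comes from simulated absorbance ladders, the CSC50 columns from
rendered, quantified plate images; the OLS R² between the branches is the
package's analogue of the near-unity cross-method agreement such assays
report.

## Command line

A launcher is installed at `system.file("cli", "dpph", package = "dpphplate")`:

```sh
dpph simulate --config sim.json --out-dir fixtures/
dpph quantify --image plate.png --layout layout.json --out spots.csv [--no-refine]
dpph fit      --measurements spots.csv --kind colour --methods halfmax,derivative --out results.csv
dpph validate --measurements spots.csv --blanks blanks.csv --kind colour --out validation.csv
dpph compare  --a sc50.csv --b csc50.csv --out agreement.csv
```

Shared flags: `--seed`, `--log-level`, `--force` (outputs are never
silently overwritten). All stages are equally reachable in R via
`run_pipeline()`.

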