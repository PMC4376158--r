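# ukaspect

Standardized evaluation of SPECT/CT studies in patients after unicondylar
knee arthroplasty (UKA). Persistent pain after UKA has many competing
explanations — loosening, malposition, impingement, progression of
osteoarthritis — and ⁹⁹ᵐTc-HDP SPECT/CT addresses them jointly: the
delayed-phase SPECT signal maps bone tracer uptake (BTU, a surrogate of
bone remodeling) onto the CT anatomy that carries the component geometry.
`ukaspect` is for imaging scientists and orthopaedic researchers who need
that combined readout to be *standardized*: the same regions, the same
statistics, the same axes and signs for every knee.

The package implements:

* **Localization scheme** — 24 scored periprosthetic regions coded
  `bone+zone+axial(+sagittal)` (e.g. `F2ip`, `T3sa`, `P1s`): 8 femoral,
  4 patellar, 12 tibial. Each region has a default summary statistic
  (max, or mean for four femoral regions) and is realized as an oriented
  voxel box anchored to the anatomical frames. Region uptake is reported
  absolutely and as a ratio to the background activity at the proximal
  femoral mid-shaft, which cancels dose and scanner gain.
* **Component position** — landmark-based anatomical frames (mechanical
  femoral axis + transepicondylar axis; tibial mechanical axis + posterior
  condylar axis) and signed projected angles of each component:
  varus-valgus, flexion-extension (femur) / posterior slope (tibia), and
  internal-external rotation, plus the femorotibial rotational mismatch
  and the tibiofemoral mechanical angle. Conventions: varus +, flexion +,
  posterior slope −, internal rotation − (flippable via
  `angle_conventions()`).
* **Reliability** — single-measure intraclass correlation coefficients
  (one-way; two-way random/absolute agreement; two-way mixed/consistency)
  with variance components, F-based confidence intervals, the
  conventional grading bands (≥ 0.81 very good, 0.61–0.80 good), and
  median signed/absolute observer differences.
* **Digital phantoms** — synthetic uptake volumes, landmark cases that
  encode known component angles exactly, and simulated rater tables with
  known variance components, so the full pipeline is testable without
  clinical data.

## Worked example

A phantom case with known truth, run through the full pipeline:

```r
library(ukaspect)

fem <- angle_report("femoral", 2.3, 15.3, -4.3)   # vv, flexion, rotation (deg)
tib <- angle_report("tibial",  7.0, -6.3, -4.7)   # vv, slope, rotation (deg)
truth <- phantom_truth(fem_angles = fem, tib_angles = tib,
                       tibiofemoral = -1.7, seed = 11)

lm    <- generate_landmark_case(fem, tib, true_tfa = -1.7)
boxes <- build_region_boxes(lm)
vol   <- generate_uptake_phantom(truth, boxes, noise_sd = 2.5)

report <- run_case(vol, lm, case_id = "example01")
report
#> <case report 'example01'>
#>   background: 49.569
#>   uptake ratios: 24 regions, range 0.61-5.37
#>   femoral vv/flex/rot: +2.3 / +15.3 / -4.3 deg
#>   tibial  vv/slope/rot: +7.0 / -6.3 / -4.7 deg
#>   rotational mismatch: +0.4 deg, tibiofemoral: -1.7 deg

head(report$uptake, 4)
#>   region statistic absolute     ratio
#> 1   F2ip      mean 30.01255 0.6054735
#> 2   F1ip      mean 39.89653 0.8048729
#> 3   F2ia      mean 50.27321 1.0142120
#> 4   F1ia       max 67.01406 1.3519420
```

Every angle comes back at its encoded value (the noiseless round-trip is
exact to ~10⁻¹⁴ degrees), and each region's ratio sits near its true
level divided by the 50-unit background — e.g. `F2ip` was painted at
ratio 0.6 and is measured at 0.605 under 5 % noise.

Observer reliability on a simulated 21-knee rating table:

```r
tab <- simulate_ratings(21, n_raters = 2, sessions = 2,
                        components = list(item_var = 9, rater_var = 0.2,
                                          residual_var = 1), seed = 11)
icc(tab[, c("U1:1", "U2:1")], "twoway_random_absolute")
#> <ICC twoway_random_absolute, single measures>
#>   value: 0.9266 (very good)
#>   95% CI: [0.8298, 0.9694]
#>   items: 21, rating columns: 2
```

With true components (item 9, rater 0.2, residual 1) the analytic ICC is
9/10.2 ≈ 0.88; the 21-item estimate of 0.93 is within sampling error, and
the grade lands in the "very good" band.

## Command line

A thin CLI wraps the same functions (`inst/exec/ukaspect`):

```sh
ukaspect scheme                       # print the 24-region table
ukaspect simulate --seed 5 --out-dir sim/
ukaspect run --volume sim/phantom.nii.gz \
             --landmarks sim/phantom_landmarks.json --out case.csv
ukaspect measure --landmarks case.json --out angles.csv
ukaspect reliability --ratings ratings.csv --out icc.csv
```

Volumes are NIfTI-1, landmarks JSON (name → `[x, y, z]` mm, scanner
space), box configuration YAML, reports CSV with a JSON sidecar at full
precision.

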