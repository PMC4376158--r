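---
title: "Methods: standardized SPECT/CT evaluation after unicondylar knee arthroplasty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized SPECT/CT evaluation after unicondylar knee arthroplasty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ukaspect)
```

## Scope and model

Patients with persistent pain after unicondylar knee arthroplasty (UKA) are
commonly imaged with ⁹⁹ᵐTc-HDP SPECT/CT: the delayed-phase SPECT signal
reflects local osteoblastic activity (bone tracer uptake, BTU), and the
co-registered CT carries the component geometry. `ukaspect` implements a
standardized evaluation of such studies with three coupled parts:

1. a **localization scheme** of 24 scored periprosthetic regions with a
   per-region summary statistic and background-normalized uptake ratios;
2. **component-position measurement** from 3D landmarks: signed projected
   angles of the femoral and tibial components against the anatomical
   reference axes, plus the rotational mismatch and the tibiofemoral
   mechanical angle;
3. **observer-reliability analysis** via intraclass correlation
   coefficients (ICC) and median observer differences.

A fourth part, the **digital phantom**, inverts parts 1 and 2: it
synthesizes volumes, landmark cases and rater tables with known ground
truth so that every pipeline stage has a parameter-recovery test without
any clinical data.

## The localization scheme

Scored regions are coded `bone + zone + axial (+ sagittal)`: bone `F`/`T`/`P`
(femur, tibia, patella), zone `1` medial, `2` lateral, `3` central around
the tibial stem, axial `i`/`s` (inferior/superior) and, on femur and tibia,
sagittal `a`/`p` (anterior/posterior). The scored grammar contains exactly
24 cells — 8 femoral, 4 patellar (no sagittal split), 12 tibial (the only
bone with zone 3):

```{r}
scheme_table()
```

Four femoral regions default to the *mean* in-box intensity and all others
to the *max*. Because a case can be made for a single statistic everywhere
(the maximum is the conventional BTU measure), a global override
(`box_config(statistic_override = "max")`) is provided; the per-region
table remains the default. Three auxiliary regions — femoral mid-shaft
background, stem tip, tibial tubercle — support the scheme but are never
scored; the mid-shaft background is the only permitted ratio denominator.

## Uptake quantification

Regions are realized as oriented boxes anchored to the anatomical frames
(`build_region_boxes()`). Femoral boxes tile the distal femur: split
medial/lateral at the mechanical axis, anterior/posterior at the
transepicondylar plane, and into two axial slabs above a configurable
distal offset. Tibial boxes tile the proximal tibia with a central zone-3
column straddling the stem axis, flanking medial/lateral zones, and two
slabs below the plateau. Patellar boxes split the patella
medial/lateral × superior/inferior. All faces are shared planes, and
membership is voxel-center inclusion with the minimum face inclusive and
the maximum face exclusive — a deterministic, interpolation-free partition
in which no voxel is counted twice. No partial-volume weighting is applied;
voxels straddling a face are attributed wholly to one side (a stated
limitation).

Box dimensions are configuration, not anatomy-derived: the defaults
(10 mm axial slabs, 40 mm peripheral-zone width, 15 mm zone-3 width,
40 mm AP depth, 20×20×30 mm background box at 50 % of the knee-to-head
distance) are plausible for adult knees and fully overridable via
`box_config()` or a YAML file (unknown keys are fatal: a silently ignored
typo in a box dimension would corrupt the science). The background
statistic is the *mean*, not the max, because a reference level should be
noise-robust; each scored region's ratio is its own statistic divided by
that background mean. Ratios are therefore invariant to global scanner
gain, which the tests verify directly.

## Component angles

All geometry runs in scanner-space millimetres; voxel indices are never
exposed. The anatomical frames are right-handed orthonormal triads
(medial→lateral, posterior→anterior, inferior→superior):

* **femoral frame** — superior axis along the mechanical femoral axis
  (knee center → femoral head center); ml axis is the transepicondylar
  axis orthogonalized against it; origin at the knee center;
* **tibial frame** — superior axis along the tibial mechanical axis
  (ankle center → tibial knee center); ml axis from the tibial posterior
  condylar axis; origin at the tibial knee center;
* **component frames** — from three fiducials per component (origin, a
  point along the component's medial→lateral reference, a point toward its
  anterior reference). Fiducial triples keep the measurement definition
  exact and testable; segmenting metal out of CT is out of scope.

Each clinical angle is a *projected angle*: the relevant component axis is
projected onto a frame plane (coronal = ml–si, sagittal = ap–si, axial =
ml–ap) and measured from the reference axis, counterclockwise about the
plane normal taken as the cross product of the plane's ordered axes.
Varus-valgus and the sagittal angle project the component's superior axis;
axial rotation projects its ml axis. The rotational mismatch is the
wrapped signed difference (femoral − tibial) of the axial rotations, and
the tibiofemoral angle is the coronal-plane angle between the two
mechanical axes in the femoral frame.

Sign conventions are not derivable from reliability tables, so they are a
design choice, centralized in `angle_conventions()` and flippable per
angle: varus positive, femoral flexion positive, tibial posterior slope
negative, internal rotation negative, tibiofemoral varus positive. One
consequence worth documenting: under signed subtraction a femoral rotation
of −4.3° and a tibial rotation of −4.7° give a mismatch of +0.4°, so a
published mismatch magnitude far exceeding the difference of mean
rotations implies a different (e.g. unsigned or per-case re-signed)
mismatch definition; this package reports the signed difference.

For the tibial sagittal reference the tibial *mechanical* axis is used.
An anatomical shaft-axis variant is deliberately not offered: with the
landmark vocabulary implemented here no second tibial axis is defined, and
silently aliasing one onto the other would be worse than omitting it.

Angles are degrees externally, radians internally, wrapped to (−180, 180].
Degeneracy guards reject coincident points and near-parallel axis pairs at
10⁻⁶ (mm, rad); finished frames must be orthonormal to 10⁻⁹.

## The phantom inverse

`generate_landmark_case()` builds a template knee (defaults: femur 400 mm,
epicondylar width 90 mm, tibia 380 mm, 12 mm joint gap — package choices,
overridable) and places component fiducials so that measurement returns
exactly the requested angles. The pose is *not* parametrized as an Euler
rotation sequence: no Euler order makes both projections of the superior
axis (coronal and sagittal) equal their respective Euler angles
simultaneously, so a rotation-based phantom would round-trip only
approximately. Instead the triad is constructed directly from the
projected-angle definition — the superior axis has frame components
(−tan α, −tan β, 1) for raw coronal/sagittal angles α, β; the ml axis is
chosen in the axial plane at the rotation angle and closed under
orthogonality; the ap axis completes the right-handed triad. This inverse
is exact for |angle| < 90° (the generator enforces a (−60°, 60°) domain,
generous for clinical malposition), and the measured round-trip error is
at machine precision (~10⁻¹⁴ degrees), comfortably inside the 10⁻⁶ °
tolerance the tests assert. The tibiofemoral angle is encoded by tilting
the ankle center in the femoral coronal plane. An optional seed applies a
random rigid transform to the whole case; all angles are invariant under
it, which the equivariance tests exploit.

`generate_uptake_phantom()` paints each region box with its true level,
the background box with the background level and everything else with a
base level, then adds Gaussian noise clipped at zero. Additive Gaussian
noise (rather than Poisson counts) reflects that a delayed-phase
reconstruction is already filtered; a Poisson mode would be a natural
extension. By default the voxel grid (4 mm isotropic) is fitted to the
boxes with a one-voxel margin, so phantoms follow the landmarks under any
rigid pose. Noiseless phantoms reproduce every ratio *exactly* because
box membership is deterministic and the background box is painted
uniformly; with noise, the mean-statistic recovery error follows the
central-limit bound 3σ/(background·√m) for an m-voxel box, which the
tests check. What the phantom does **not** emulate: the SPECT point-spread
function, attenuation, scatter, metal artifacts, and anatomically shaped
(non-box) uptake — passing phantom tests therefore validates the
*measurement pipeline*, not robustness to real acquisition physics.

`simulate_ratings()` draws `value(i,r,s) = μ + b_i + c_r + e_irs` with
independent Gaussian item, rater and residual effects, attaching the
analytic one-way ICC `σ²_item/(σ²_item+σ²_rater+σ²_residual)` as metadata.

## ICC models and reliability bands

`icc()` computes single-measure ICCs from the two-way items × raters mean
squares (MSR rows, MSC columns, MSE residual, MSW within-item):

* one-way: `(MSB − MSW) / (MSB + (k−1)·MSW)`;
* two-way random, absolute agreement:
  `(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))`;
* two-way mixed, consistency: `(MSR − MSE) / (MSR + (k−1)·MSE)`.

The source data never state which form was used for published UKA
reliability tables, so the package picks the standard Shrout–Fleiss
pairing and documents it: *intra*-observer (test-retest within one
reader) uses two-way mixed consistency — a stable personal offset between
two sessions should not count against a reader; *inter*-observer uses
two-way random absolute agreement — a systematic shift between readers is
real disagreement. Both choices are selectable arguments, not constants.
When observers read twice, the inter-observer table uses each observer's
first session by default (`session_policy = "mean_of_sessions"` averages
them instead). Negative estimates are reported as computed and flagged,
never truncated: clipping would bias the simulation-based validation.
All-identical tables raise an error rather than returning 1 by fiat —
zero total variance carries no reliability information. Estimates are
graded on the conventional bands (≥ 0.81 "very good", 0.61–0.80 "good")
and accompanied by F-based 95 % confidence intervals. "Absolute" and
"relative" uptake reliability are simply two variable streams (raw
intensities vs background ratios) fed to the same estimator.

## Numerical choices and problem sizes

* Voxel membership: half-open boxes make partitions exact and the
  brute-force voxel-loop oracle reproducible bit-for-bit for the max
  statistic and to 10⁻¹² relative for the mean.
* The validation suite runs 1,000-case angle round-trips, 50 random
  volume/box oracle comparisons, 100 random ICC tables against a
  separately coded ANOVA oracle, and 200 simulation seeds at n = 500
  items, k = 2 raters for the ICC 0.9 recovery check (analytic value
  recovered within ±0.03 in ≥ 95 % of seeds). These sizes give tight
  Monte-Carlo bounds while keeping the whole suite under a minute of
  compute on one core.
* Determinism: generators save and restore the session RNG state, so a
  seed fully determines the phantom and never perturbs user code.

## Known limitations

No DICOM ingestion (convert externally to NIfTI), no automatic landmark
detection or metal segmentation, no SUV/attenuation/scatter handling, no
partial-volume weighting, no TKA scheme, and no sample-size planning for
reliability studies. The phantom validates geometry and bookkeeping, not
image physics; reliability of the scheme on real readers must come from
real rating tables fed to `reliability_report()`.
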