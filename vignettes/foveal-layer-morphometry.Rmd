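---
title: "Foveal layer morphometry on synthetic SD-OCT B-scans: models and design choices"
author: "foveaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal layer morphometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science behind each stage of the package — the
phantom and cohort generators, the graph shortest-path segmentation, the
magnification-corrected foveal sampling and the group-comparison statistics —
and records the design choices that were genuinely open, with their
rationale. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. What the synthetic B-scan emulates

An SD-OCT B-scan of the macula shows the retina as a stack of bands of
alternating reflectivity. The phantom (`phantom_spec()`, `generate_bscan()`)
renders ten intensity compartments — vitreous, eight layers (NFL, GCL+IPL,
INL, OPL, HFL+ONL, MEZ, OS, IZ+RPE), choroid — separated by nine boundary
curves:

* **Geometry.** The periphery is piecewise flat; the left and right image
  sides can carry different layer stacks (anchored at ±`side_anchor_um`,
  default 500 µm, linear in between) so nasal/temporal and superior/inferior
  asymmetry is expressible. A Gaussian depression of lateral sigma
  `pit_radius` (default 180 µm, i.e. negligible depression beyond ~500 µm)
  pulls boundaries B1–B5 toward a common pit-floor row, so the four inner
  layers have exactly zero ground-truth thickness at the pit center — the
  anatomical definition of the foveal center. Outer boundaries B6–B9 stay
  flat (optionally anchored centrally), matching the qualitative anatomy in
  which the outer retina runs through the pit.
* **Default scales and sizes.** 496 × 512 px at 3.87 µm/px axial and
  5.7 µm/px lateral — typical for the spectral-domain instrument class; no
  pixel geometry is authoritative, so all are configurable. Default boundary
  spacing reproduces the reference control-eye nasal layer thicknesses, and
  the default pit depth makes the central total equal the reference control
  central total (≈133 µm).
* **Intensities.** Ten gray levels (10, 170, 100, 50, 130, 40, 180, 80, 200,
  70 on 0–255) giving every boundary a defined gradient polarity with at
  least 50 gray levels of contrast. Adjacent-layer polarity alternates
  except at B2/B3, where two consecutive light-to-dark steps mimic the real
  NFL → GCL+IPL → INL brightness cascade; the per-boundary polarity table in
  `seg_config()` is matched to this scheme and both are configurable
  together.
* **Rendering and noise.** Compartments are filled with anti-aliased
  partial-volume coverage (a pixel straddling a boundary mixes the two
  intensities by overlap), blurred with a Gaussian point-spread surrogate
  (`blur_sigma`, default 1 px ≈ 3.9 µm — about the axial resolution of the
  instrument class), then multiplied by mean-1 gamma speckle with coefficient
  of variation `noise_level` (default 0.1). Multiplicative gamma is the
  standard first-order model of fully developed OCT speckle.
* **What it does not emulate.** Retinal vessels and their shadows, motion
  artifacts, depth-dependent signal roll-off, curvature of the posterior
  pole, 3-D volume context. Passing tests on phantoms therefore demonstrate
  correctness of the operators under controlled contrast and noise, not
  clinical-grade robustness on patient scans.

## 2. What the synthetic cohort emulates

`generate_cohort()` draws a three-group cohort (amblyopic, fellow, control;
default n = 18 eyes each) whose thickness, biometry and acuity marginals
follow the reference tables `foveal_thickness_reference()` and
`cohort_baseline_reference()` — 41 region × layer Gaussian cells per group
plus spherical equivalent, axial length and logMAR acuity. Design points:

* Amblyopic and fellow rows are generated pairwise (same subject id, age,
  sex); controls are independent subjects, mirroring a design that analyzes
  one eye per control. Ages are normal, truncated to the 5–12 y inclusion
  band (7.8 ± 1.9 y for amblyopic subjects, 7.7 ± 1.0 y for controls); sex
  is Bernoulli at the reference group proportions (14/18 and 11/18 male).
* `paired_eye_correlation` correlates the thickness z-scores of a subject's
  two eyes. The default is 0, matching the independence assumption of the
  downstream analysis (eyes enter the ANCOVA as independent groups); raising
  it lets users quantify what that assumption costs.
* Every cell is drawn from its own marginal, so a subject's drawn `total`
  column is **not** the sum of the drawn layer cells (the reference table's
  totals and layers are separately published summaries). Thickness tables
  measured by the imaging lane are internally consistent instead: there,
  total ≡ sum of the eight layers by construction.
* Draws are truncated below at 0.1 µm (thicknesses are physical lengths;
  some reference SDs are large enough to produce negatives otherwise), and
  truncation is by inverse-CDF so the draw count — hence the seeded stream —
  is deterministic, and `sd = 0` reproduces means exactly.

## 3. Segmentation: graph construction and sequential protocol

For each polarity the vertical central difference of the (optionally
smoothed, `smoothing_sigma` default 0.8 px) image is half-rectified and
min–max normalized to [0, 1]. A boundary is the minimum-cost left-to-right
path where node weight is `w = 1 − g + w_min` (`w_min = 1e−5`), an edge
between adjacent columns costs `w(a) + w(b) + step_penalty·|Δrow|`, vertical
steps are bounded by `max_jump` (default 1 px; with the virtual zero-cost
endpoint columns this is the classic 8-connectivity construction), and the
reported cost is the sum of edge costs. The dynamic program is exact; the
test suite checks it against exhaustive enumeration on hundreds of small
random instances.

`step_penalty` (default 1e−3) is a deliberate addition to the textbook cost:
inside the foveal pit the inner-boundary gradients vanish and the pure
shortest path is massively tied; the penalty makes the optimum unique and
straight in gradient-free regions while being ~100× too small to perturb any
contrast-driven decision. It is included in the reported cost and in the
oracle.

The nine boundaries are found sequentially, strongest contrast first:
B9 → B1 → B6 → B8 → B7 → B5 → B2 → B4 → B3 under the default intensity
scheme. After each acceptance the remaining search bands are restricted to
respect anatomical ordering, with three refinements worth recording:

* **Polarity-aware margins.** The exclusion margin (`margin_um`, default
  8 µm ≈ 2 px) applies only between boundaries that share a gradient map; an
  opposite-polarity neighbour cannot attract a path, and a margin there
  would prevent the genuine coalescence of B1–B5 at the pit. With margins on
  same-polarity pairs a weak boundary (e.g. B3, contrast 50) cannot lock
  onto a strong neighbour's edge (B2, contrast 70) whose blurred flank at
  2 px falls well below its own peak.
* **Minimum retinal thickness.** Once Bruch's membrane is accepted, the ILM
  is searched at least `min_retina_um` (default 100 µm) above it. Without
  this prior a locally thin NFL can weaken the vitreoretinal edge below the
  ELM's contrast and the ILM path absconds to the outer retina; no human
  retina is thinner than ~100 µm at the foveola, so the prior is safe.
* **Band relaxation and clamping.** Derived bands are relaxed to a slope of
  `max_jump` per column so they are always traversable, bands inverted by
  the pinch collapse onto the boundary above, and any residual crossing
  after sub-pixel refinement (per-column parabolic fit of the gradient over
  ±1 px) is resolved by clamping — producing the zero-thickness columns that
  the foveal pit genuinely has, rather than a failure.

A pre-flattening pass (`flatten = TRUE`) aligns columns to a provisional
Bruch's membrane for steeply curved inputs; the default phantom is flat, so
it is off by default.

**Known limitation.** Where compressed inner layers fall below the
point-spread width (the pit walls), partial-volume slivers bias the weaker
boundaries by 1–4 px, and exactly at the foveola the estimated inner
boundaries ride ~1–4 px below the ILM instead of coinciding with it. This is
a physics-of-the-image limit, not a search failure; it motivates the 20 µm
inner-absence threshold below.

## 4. Foveal center, magnification and sampling

The foveal center is defined anatomically: the column of minimum smoothed
total thickness among columns whose smoothed inner-layer sum
(NFL + GCL/IPL + INL + OPL) is below `inner_absence_threshold`. Two numeric
choices:

* **Threshold 20 µm** (not a few µm): ground-truth profiles pinch to exactly
  0, but estimated profiles keep the partial-volume residual of ~15 µm
  described above. Peripheral inner thickness is ~130 µm, so 20 µm still
  isolates an unambiguous pit region.
* **Parabolic localization.** The pit bottom is locally quadratic but very
  flat (the total changes by well under 1 µm over ±3 columns), so the raw
  argmin wanders under speckle. The default fits a parabola to the smoothed
  total over the inner-absence region and takes its vertex;
  `method = "argmin"` gives the plain restricted argmin with the
  median-of-plateau tie-break. The 5-column moving average is kept for both.

Bennett's formula enters only laterally: `q = 0.01306·(AL − 1.82)` and
`corrected_scale = nominal · q(AL)/q(AL_ref)` with `AL_ref = 23.95 mm` as
the instrument's assumed model eye (the true value is proprietary; the ratio
form makes the choice second-order). OCT axial distances are interferometric
and magnification-independent to first order, so thickness values are never
rescaled — only the pixel offset corresponding to 0.5 mm changes, by
nearest-column sampling (linear interpolation by flag). Central values
average the horizontal- and vertical-scan center values; nasal/temporal and
superior/inferior assignment comes from the scan sidecar's declared
column-direction fields, never from pixel content.

## 5. Statistics

Each region × layer outcome is analyzed by its own univariate ANCOVA
`thickness ~ group + age + sex` (age centered, sex as male indicator), the
group term tested by the extra-sum-of-squares F, and the three pairwise
contrasts of covariate-adjusted means tested by model-based t-tests with
Bonferroni factor 3 capped at 1 (`">0.999"` above 0.9995, three decimals
otherwise). Per-outcome families (not pooling across layers) are the only
reading consistent with a reference table that shows many `>0.999` entries
next to a surviving p = 0.010; a genuinely multivariate first-stage test is
out of scope. Baseline variables use the Welch t-test — the safer default
when only "t test" is specified and group variances differ; correlations are
Pearson with the t-transform p-value on n − 2 df, computed on amblyopic eyes
by default (configurable; the contributing eye set is not standardized).
Interocular acuity difference (amblyopic − fellow logMAR per subject) is the
severity measure offered for correlation.

The type-I error of this stage is checked by simulation: under a null
generator (identical group distributions) the group test rejects at the
nominal 5% within Monte-Carlo error at 1 000 replicates.

## 6. Problem sizes and numerical conventions

The test suite runs phantoms at 496 × 512 (default geometry) where the claim
concerns the default instrument model and 320 × 360 where only operator
correctness matters; stochastic suites use 5–20 seeded phantoms, cohort
moment checks use n = 2 000–10 000, and calibration uses 1 000 ANCOVA
replicates — sizes at which the Monte-Carlo bands in the tests are
3-sigma-safe. All randomness flows through explicit integer seeds
(`withr::with_seed`), so every artifact, including written CSVs, is
byte-reproducible. CSVs are UTF-8, dot-decimal, with a schema-version
comment header; images round-trip as 16-bit TIFF (or 8-bit PNG) with a JSON
sidecar carrying eye, meridian, scales, axial length and column-direction
conventions.

## 7. Other limitations

* The pipeline treats single B-scans per meridian; no volume averaging, no
  ETDRS ring summaries (the analysis samples points, not rings).
* Eyes are independent observations in the statistics even when generated
  paired; mixed-effects alternatives are out of scope by design.
* The segmentation is a faithful member of the graph shortest-path /
  dynamic-programming class with documented operators; it is not a bit-exact
  clone of any particular clinical implementation.
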