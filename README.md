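# foveaseg

Graph-based intra-retinal layer segmentation and foveal morphometry for
SD-OCT B-scans, with a fully synthetic test bed and the statistical stage of
a three-group amblyopia study.

## The problem

Whether the retina itself participates in amblyopia is an open question.
Studies that compare foveal layer thicknesses between unilateral amblyopic
eyes, their fellow eyes and the eyes of visually normal children report
differences of only a few micrometers, so results hinge on three technical
steps that this package implements as one reproducible pipeline:

1. **Boundary segmentation.** Nine intra-retinal boundaries (ILM, NFL/GCL+IPL,
   IPL/INL, INL/OPL, OPL/HFL+ONL, ELM, MEZ/OS, OS/IZ+RPE, Bruch's membrane)
   are detected on each B-scan by minimum-cost path search on a graph whose
   node weights are `w = 1 − g + w_min`, with `g` a polarity-split
   (dark-to-light / light-to-dark) normalized vertical gradient map. Paths
   run left to right with bounded vertical steps and free endpoints (virtual
   zero-cost columns), and boundaries are found sequentially, each restricted
   by those already accepted, yielding eight layer thickness profiles
   `t_k(x) = (B_{k+1}(x) − B_k(x)) · s_axial`.
2. **Magnification correction.** Lateral geometry is rescaled per eye with
   Bennett's formula `q = 0.01306 · (AL − 1.82)` in ratio form against the
   instrument's model eye, so the 0.5 mm sampling eccentricity is anatomically
   correct in short (hyperopic, amblyopic) and long eyes alike.
3. **Group comparison.** Thicknesses at the foveal center and at 0.5 mm in
   four quadrants are compared across the three groups by per-outcome ANCOVA
   (`thickness ~ group + age + sex`), Bonferroni-corrected pairwise contrasts
   (family of 3, capped at 1, `">0.999"` display convention), Welch t-tests
   for biometry/acuity and Pearson correlations.

Because no patient images are distributable, the package ships a first-class
synthetic module: B-scan phantoms with sub-pixel ground-truth boundaries, a
Gaussian foveal pit where the four inner layers vanish, alternating-contrast
layer intensities, Gaussian blur and multiplicative gamma speckle; and
three-group cohorts drawn from published group means ± SDs
(`foveal_thickness_reference()`, `cohort_baseline_reference()`), with paired
amblyopic/fellow eyes and configurable covariate effects.

## Worked example

```r
library(foveaseg)

## phantom with speckle + segmentation, judged against its own ground truth
ph  <- generate_bscan(phantom_spec(noise_level = 0.1, seed = 1))
est <- segment_layers(ph$scan)
boundary_error(ph$truth, est)
#>   boundary mae_um rmse_um max_um
#> 1       B1  0.637   0.941  3.362
#> 2       B2  1.715   2.793 13.316
#> ...
#> 9       B9  0.609   0.725  2.058

## magnification-corrected foveal sampling (two meridians of one eye)
v   <- generate_bscan(phantom_spec(meridian = "vertical", noise_level = 0.1, seed = 2))
lat <- corrected_lateral_scale(5.7, axial_length = 21.77)   # 5.1385 um/px
fs  <- sample_fovea(
  boundaries_to_thickness(est, lateral_scale = lat),
  boundaries_to_thickness(segment_layers(v$scan), lateral_scale = lat))
fs
#> <foveal_sample> eye OD, centers h=256 v=256, 500 um eccentricity
#>   central total 133.8 um; peripheral totals: nasal 214.6, temporal 213.7,
#>   superior 213.4, inferior 213.0

## three-group cohort at the reference distribution parameters + ANCOVA
coh <- generate_cohort(cohort_spec(seed = 1))
ancova_group_compare(coh, c("nasal", "nfl"))
#> ANCOVA (thickness ~ group + age + sex): nasal_nfl
#>   group F(2, 49) = 6.346, p = 0.004
#>   amblyopic   18.43 +/-  1.52 um (adjusted  18.44), n = 18
#>   fellow      16.93 +/-  1.90 um (adjusted  16.94), n = 18
#>   control     16.41 +/-  1.77 um (adjusted  16.38), n = 18
#>   amblyopic_vs_fellow    diff   1.50 um, Bonferroni p = 0.042
#>   amblyopic_vs_control   diff   2.06 um, Bonferroni p = 0.004
#>   fellow_vs_control      diff   0.56 um, Bonferroni p = >0.999

## the reference worked example: nasal NFL amblyopic - control
group_mean_difference(foveal_thickness_reference(), c("nasal", "nfl"),
                      "amblyopic", "control")
#> [1] 1.88
```

The per-boundary MAE under speckle stays well below the instrument's ~3 µm
axial resolution; the central total of ~133 µm and the sampled quadrant
totals of ~215 µm match the configured reference geometry; and the ANCOVA on
a cohort drawn at the reference parameters flags the nasal NFL
amblyopic-vs-control difference, the same cell the reference table singles
out.

`run_pipeline(pipeline_config(seed = 1), "out/")` runs the whole chain —
simulate cohort → render per-eye phantoms → segment → correct magnification →
sample fovea → ANCOVA report + correlations — and writes schema-versioned
CSVs that are byte-identical under a fixed seed. A thin CLI wrapper with
`simulate`/`segment`/`measure`/`compare`/`run` subcommands is installed at
`inst/cli/foveaseg.R`.

## Layout

- `R/` — phantoms + cohorts (`phantom.R`, `cohort.R`, `reference.R`),
  segmentation (`segmentation.R`), morphometry (`metrics.R`), statistics
  (`stats.R`), file round-tripping (`io.R`), orchestration (`pipeline.R`).
- `vignettes/foveal-layer-morphometry.Rmd` — models, assumptions, parameter
  choices, limitations.
- `tests/testthat/` — unit, property and end-to-end suites with independent
  oracles (exhaustive path enumeration, normal-equations ANCOVA, closed-form
  Welch/Pearson).
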