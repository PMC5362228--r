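## Reference group statistics for a three-group pediatric anisometropic
## amblyopia study population (unilateral amblyopic eyes, fellow eyes,
## age-matched control eyes; n = 18 per group). These parameterize the
## cohort simulator and provide the worked-example means for
## group_mean_difference().

#' Reference foveal layer thickness distribution parameters
#'
#' Group means and standard deviations (in micrometers) of foveal layer
#' thicknesses for a three-group pediatric anisometropic amblyopia study
#' population: unilateral amblyopic eyes, their fellow eyes, and age-matched
#' control eyes (n = 18 each). Central-fovea entries cover the total and the
#' four outer layers present at the foveal center (HFL+ONL, MEZ, OS,
#' IZ+RPE); peripheral entries cover all eight layers plus the total at
#' 0.5 mm eccentricity in the nasal, temporal, superior and inferior
#' quadrants. Used as the default `thickness_params` of [cohort_spec()].
#'
#' @return A data frame with columns `region`, `layer`, `group`, `mean`,
#'   `sd` (123 rows: 41 region-layer cells by 3 groups).
#' @seealso [cohort_baseline_reference()], [generate_cohort()],
#'   [group_mean_difference()]
#' @export
#' @examples
#' ref <- foveal_thickness_reference()
#' subset(ref, region == "nasal" & layer == "nfl")
foveal_thickness_reference <- function() {
  ## columns: amblyopic mean, sd; fellow mean, sd; control mean, sd
  vals <- matrix(c(
    ## central fovea
    133.58, 8.16, 132.85, 9.48, 133.31, 6.31,   # total
    65.11, 8.19, 64.46, 9.11, 66.58, 6.49,      # hfl_onl
    16.80, 1.15, 17.11, 1.73, 15.96, 0.85,      # mez
    26.56, 1.13, 26.02, 1.04, 25.86, 0.92,      # os
    25.09, 1.83, 25.25, 1.52, 24.90, 1.76,      # iz_rpe
    ## nasal, 0.5 mm
    224.95, 9.92, 217.78, 11.43, 215.10, 12.36, # total
    18.26, 1.68, 17.15, 1.82, 16.38, 2.31,      # nfl
    43.16, 5.67, 39.91, 6.77, 38.81, 7.14,      # gcl_ipl
    20.08, 2.55, 20.52, 2.57, 20.77, 3.14,      # inl
    12.76, 2.65, 15.99, 6.77, 12.57, 3.89,      # opl
    65.81, 5.54, 60.17, 8.43, 62.63, 6.00,      # hfl_onl
    16.29, 1.01, 16.32, 1.45, 16.29, 1.52,      # mez
    24.05, 1.38, 23.54, 1.60, 22.84, 2.00,      # os
    24.51, 1.84, 24.15, 2.33, 24.82, 2.08,      # iz_rpe
    ## temporal, 0.5 mm
    216.87, 11.88, 213.39, 10.93, 208.22, 11.15,
    16.93, 1.60, 16.50, 2.29, 15.57, 2.32,
    38.25, 5.57, 38.95, 6.07, 36.80, 6.17,
    19.13, 3.76, 18.75, 3.18, 19.44, 3.17,
    20.02, 10.26, 13.74, 5.04, 17.10, 9.83,
    59.19, 11.48, 61.60, 6.74, 56.02, 13.56,
    16.22, 1.08, 16.53, 0.74, 16.52, 1.28,
    23.87, 2.00, 23.32, 2.17, 22.98, 2.50,
    24.23, 3.50, 23.97, 2.95, 23.80, 2.62,
    ## superior, 0.5 mm
    229.06, 9.45, 221.44, 14.40, 221.17, 10.71,
    16.66, 3.27, 17.77, 3.75, 17.41, 4.72,
    48.27, 6.88, 47.85, 6.03, 47.15, 7.05,
    25.27, 3.35, 23.93, 3.12, 22.81, 2.90,
    22.46, 8.67, 21.37, 6.61, 23.71, 6.92,
    52.13, 14.20, 46.18, 13.84, 47.52, 8.39,
    16.98, 2.59, 17.67, 3.63, 16.76, 1.48,
    23.38, 1.54, 22.74, 1.28, 22.42, 3.77,
    23.88, 2.56, 23.90, 1.72, 23.98, 3.05,
    ## inferior, 0.5 mm
    230.76, 9.86, 221.78, 11.48, 219.90, 12.51,
    17.48, 2.81, 18.09, 2.50, 18.63, 4.45,
    50.76, 5.67, 46.59, 5.93, 45.88, 8.29,
    25.54, 1.82, 23.54, 3.66, 22.40, 3.68,
    16.94, 3.48, 19.97, 8.37, 18.36, 5.78,
    55.77, 7.59, 49.37, 9.23, 52.86, 8.97,
    16.78, 2.34, 17.46, 3.70, 16.08, 1.29,
    23.15, 2.18, 22.86, 1.48, 22.26, 3.01,
    24.30, 2.60, 23.85, 2.73, 23.43, 3.32
  ), ncol = 6, byrow = TRUE)

  central_layers <- c("total", "hfl_onl", "mez", "os", "iz_rpe")
  quad_layers <- c("total", .LAYERS)
  region <- c(rep("central", length(central_layers)),
              rep(.QUADS, each = length(quad_layers)))
  layer <- c(central_layers, rep(quad_layers, times = length(.QUADS)))
  stopifnot(nrow(vals) == length(layer))

  out <- data.frame(
    region = rep(region, each = 3L),
    layer = rep(layer, each = 3L),
    group = rep(.GROUPS, times = nrow(vals)),
    mean = as.vector(t(vals[, c(1, 3, 5)])),
    sd = as.vector(t(vals[, c(2, 4, 6)])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Reference baseline (biometry and acuity) distribution parameters
#'
#' Group means and standard deviations of spherical-equivalent refraction
#' (diopters), axial length (mm) and best-corrected visual acuity (logMAR)
#' for the same three-group study population as
#' [foveal_thickness_reference()]. Default `baseline_params` of
#' [cohort_spec()].
#'
#' @return A data frame with columns `variable`, `group`, `mean`, `sd`.
#' @export
cohort_baseline_reference <- function() {
  data.frame(
    variable = rep(c("se_d", "axial_length_mm", "va_logmar"), each = 3L),
    group = rep(.GROUPS, times = 3L),
    mean = c(4.44, 0.75, 0.00,
             21.77, 23.17, 22.97,
             0.48, 0.00, 0.01),
    sd = c(1.57, 0.98, 0.29,
           0.68, 0.75, 0.69,
           0.19, 0.01, 0.03),
    stringsAsFactors = FALSE
  )
}
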