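## Synthetic three-group cohorts ---------------------------------------------

#' Specify a synthetic three-group cohort
#'
#' Parameters for [generate_cohort()], which draws a cohort of amblyopic
#' eyes, fellow eyes and control eyes with the statistical structure the
#' group-comparison stage assumes. Amblyopic and fellow rows are generated
#' pairwise (same subject id, age and sex); control subjects are
#' independent, mirroring a design that analyzes one eye per control.
#'
#' @param n_per_group Number of eyes per group.
#' @param thickness_params Data frame with columns `region`, `layer`,
#'   `group`, `mean`, `sd` (micrometers) giving the Gaussian parameters of
#'   every thickness measurement for each of the three groups. Default:
#'   [foveal_thickness_reference()].
#' @param baseline_params Data frame with columns `variable`
#'   (`se_d`, `axial_length_mm`, `va_logmar`), `group`, `mean`, `sd`.
#'   Default: [cohort_baseline_reference()].
#' @param age_mean,age_sd Age distribution (years) for amblyopic subjects
#'   and controls; scalars or named vectors with entries `amblyopic` and
#'   `control`. Defaults 7.8 +/- 1.9 y and 7.7 +/- 1.0 y.
#' @param age_range Ages are truncated to this range (years); default
#'   `c(5, 12)`, the study inclusion band.
#' @param sex_proportion Fraction male; scalar or named vector
#'   (`amblyopic`, `control`). Defaults 14/18 and 11/18.
#' @param paired_eye_correlation Correlation `rho` between the thickness
#'   deviations (z-scores) of a subject's amblyopic and fellow eye.
#'   Default 0, matching an analysis that treats eyes as independent;
#'   raise it to probe the consequence of interocular pairing.
#' @param age_effect Linear age slope added to every thickness
#'   (micrometers/year, about the group age mean). Default 0.
#' @param sex_effect Additive male offset on every thickness (micrometers).
#'   Default 0.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 18L,
                        thickness_params = foveal_thickness_reference(),
                        baseline_params = cohort_baseline_reference(),
                        age_mean = c(amblyopic = 7.8, control = 7.7),
                        age_sd = c(amblyopic = 1.9, control = 1.0),
                        age_range = c(5, 12),
                        sex_proportion = c(amblyopic = 14 / 18,
                                           control = 11 / 18),
                        paired_eye_correlation = 0,
                        age_effect = 0,
                        sex_effect = 0,
                        seed = NULL) {
  per_group <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x)))
      x <- c(amblyopic = unname(x), control = unname(x))
    if (!all(c("amblyopic", "control") %in% names(x)))
      stop(nm, " must be a scalar or name entries 'amblyopic' and 'control'")
    x[c("amblyopic", "control")]
  }
  spec <- structure(list(
    n_per_group = as.integer(n_per_group),
    thickness_params = thickness_params,
    baseline_params = baseline_params,
    age_mean = per_group(age_mean, "age_mean"),
    age_sd = per_group(age_sd, "age_sd"),
    age_range = age_range,
    sex_proportion = per_group(sex_proportion, "sex_proportion"),
    paired_eye_correlation = paired_eye_correlation,
    age_effect = age_effect, sex_effect = sex_effect,
    seed = seed
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_group < 0L) stop("n_per_group must be >= 0")
  if (abs(spec$paired_eye_correlation) > 1)
    stop("paired_eye_correlation must be in [-1, 1]")
  if (any(spec$age_sd < 0)) stop("age_sd must be >= 0")
  if (any(spec$sex_proportion < 0 | spec$sex_proportion > 1))
    stop("sex_proportion must be in [0, 1]")
  tp <- spec$thickness_params
  need <- c("region", "layer", "group", "mean", "sd")
  if (!all(need %in% names(tp)))
    stop("thickness_params must have columns ",
         paste(need, collapse = ", "))
  if (any(tp$sd < 0)) stop("thickness_params sd must be >= 0")
  cells <- unique(tp[, c("region", "layer")])
  for (g in .GROUPS) {
    have <- tp[tp$group == g, c("region", "layer")]
    if (nrow(merge(cells, have)) != nrow(cells))
      stop("missing group parameters: group '", g,
           "' does not cover every region x layer cell")
  }
  bp <- spec$baseline_params
  if (!all(c("variable", "group", "mean", "sd") %in% names(bp)))
    stop("baseline_params must have columns variable, group, mean, sd")
  if (any(bp$sd < 0)) stop("baseline_params sd must be >= 0")
  for (g in .GROUPS) {
    miss <- setdiff(c("se_d", "axial_length_mm", "va_logmar"),
                    bp$variable[bp$group == g])
    if (length(miss))
      stop("missing group parameters: baseline variable(s) ",
           paste(miss, collapse = ", "), " for group '", g, "'")
  }
  invisible(spec)
}

#' Generate a synthetic cohort table
#'
#' Draws `n_per_group` eyes per group. Thickness values are Gaussian at the
#' configured means/SDs, truncated below at 0.1 micrometers (thicknesses are
#' physical lengths); the amblyopic and fellow eye of one subject share id,
#' age and sex, and their thickness z-scores are correlated with
#' `paired_eye_correlation`. Optional linear age and sex covariate effects
#' are added to every thickness. Fully reproducible under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of class `oct_cohort`: columns `subject`, `group`,
#'   `age`, `sex`, `se_d`, `axial_length_mm`, `va_logmar`, then one
#'   `region_layer` column per thickness measurement (micrometers).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 4, seed = 1))
#' coh[, 1:8]
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n <- spec$n_per_group
  tp <- spec$thickness_params
  bp <- spec$baseline_params
  rho <- spec$paired_eye_correlation
  cells <- unique(tp[, c("region", "layer")])
  meas <- paste(cells$region, cells$layer, sep = "_")

  with_opt_seed(spec$seed, {
    age_a <- rnorm_trunc(n, spec$age_mean[["amblyopic"]],
                         spec$age_sd[["amblyopic"]],
                         spec$age_range[1], spec$age_range[2])
    sex_a <- ifelse(runif(n) < spec$sex_proportion[["amblyopic"]], "M", "F")
    age_c <- rnorm_trunc(n, spec$age_mean[["control"]],
                         spec$age_sd[["control"]],
                         spec$age_range[1], spec$age_range[2])
    sex_c <- ifelse(runif(n) < spec$sex_proportion[["control"]], "M", "F")

    draw_base <- function(grp) {
      sapply(c("se_d", "axial_length_mm", "va_logmar"), function(v) {
        row <- bp[bp$variable == v & bp$group == grp, ]
        row$mean[1] + row$sd[1] * rnorm(n)
      }, simplify = FALSE)
    }
    base_a <- draw_base("amblyopic")
    base_f <- draw_base("fellow")
    base_c <- draw_base("control")

    cov_shift <- function(age, sex, grp) {
      mu_age <- spec$age_mean[[if (grp == "control") "control" else "amblyopic"]]
      spec$age_effect * (age - mu_age) + spec$sex_effect * (sex == "M")
    }
    sh_a <- cov_shift(age_a, sex_a, "amblyopic")
    sh_c <- cov_shift(age_c, sex_c, "control")

    th_a <- th_f <- th_c <- matrix(NA_real_, n, length(meas),
                                   dimnames = list(NULL, meas))
    for (i in seq_along(meas)) {
      pa <- tp[tp$region == cells$region[i] & tp$layer == cells$layer[i], ]
      pr <- function(g) pa[pa$group == g, ]
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      zc <- rnorm(n)
      th_a[, i] <- pmax(0.1, pr("amblyopic")$mean + pr("amblyopic")$sd * z1 + sh_a)
      th_f[, i] <- pmax(0.1, pr("fellow")$mean + pr("fellow")$sd * z2 + sh_a)
      th_c[, i] <- pmax(0.1, pr("control")$mean + pr("control")$sd * zc + sh_c)
    }

    mk <- function(subject, group, age, sex, base, th) {
      group <- rep(group, length.out = length(subject))
      cbind(data.frame(subject = subject, group = group, age = age, sex = sex,
                       se_d = base$se_d,
                       axial_length_mm = base$axial_length_mm,
                       va_logmar = base$va_logmar,
                       stringsAsFactors = FALSE),
            as.data.frame(th))
    }
    sid_a <- sprintf("A%03d", seq_len(n))
    sid_c <- sprintf("C%03d", seq_len(n))
    out <- rbind(
      mk(sid_a, "amblyopic", age_a, sex_a, base_a, th_a),
      mk(sid_a, "fellow", age_a, sex_a, base_f, th_f),
      mk(sid_c, "control", age_c, sex_c, base_c, th_c)
    )
    if (n == 0L) out <- out[0, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "schema_version") <- .SCHEMA_VERSION
    class(out) <- c("oct_cohort", "data.frame")
    out
  })
}

#' Pivot a cohort table to long thickness format
#'
#' @param cohort An `oct_cohort` (or compatible wide data frame).
#' @return Data frame with columns `subject`, `group`, `region`, `layer`,
#'   `thickness_um` — the long-format interface of the statistics stage.
#' @export
cohort_long <- function(cohort) {
  meas <- thickness_columns(cohort)
  if (nrow(cohort) == 0L || length(meas) == 0L) {
    return(data.frame(subject = character(0), group = character(0),
                      region = character(0), layer = character(0),
                      thickness_um = numeric(0), stringsAsFactors = FALSE))
  }
  rl <- split_measurement(meas)
  out <- do.call(rbind, lapply(seq_along(meas), function(i) {
    data.frame(subject = cohort$subject, group = cohort$group,
               region = rl$region[i], layer = rl$layer[i],
               thickness_um = cohort[[meas[i]]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## thickness measurement columns of a wide cohort table
thickness_columns <- function(cohort) {
  known <- c("subject", "group", "age", "sex", "se_d", "axial_length_mm",
             "va_logmar", "eye")
  setdiff(names(cohort), known)
}

split_measurement <- function(meas) {
  region <- sub("_.*$", "", meas)
  layer <- sub("^[^_]+_", "", meas)
  list(region = region, layer = layer)
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf("<oct_cohort> %d eyes (%s), %d thickness measurements\n",
              nrow(x),
              paste(sprintf("%s: %d", names(table(x$group)), table(x$group)),
                    collapse = ", "),
              length(thickness_columns(x))))
  invisible(x)
}
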