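## End-to-end orchestration ---------------------------------------------------

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Exactly one input source
#' is used: `simulate` (the default; synthetic cohort + phantom scans) or
#' `input` (paths to user-supplied scans and a cohort CSV). The global
#' `seed` propagates to every stochastic stage.
#'
#' @param seed Global integer seed.
#' @param simulate List: `n_per_group`, plus optional overrides
#'   `paired_eye_correlation`, `age_effect`, `sex_effect`,
#'   `thickness_params`, and a `phantom` sub-list (`image_height`,
#'   `image_width`, `axial_scale`, `lateral_scale`, `noise_level`,
#'   `blur_sigma`, `pit_radius`). Set to `NULL` when `input` is given.
#' @param input List with `scans` (data frame or list of image/sidecar
#'   paths) and `cohort_csv`, or `NULL` to simulate.
#' @param segmentation List of [seg_config()] overrides.
#' @param magnification List: `enabled` (default `TRUE`) and
#'   `reference_axial_length` (default 23.95 mm).
#' @param stats List: `correlation_group`, `correlation_x`, `welch`.
#' @param verbose Emit per-stage progress messages on stderr.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(n_per_group = 18L),
                            input = NULL,
                            segmentation = list(),
                            magnification = list(
                              enabled = TRUE,
                              reference_axial_length = 23.95),
                            stats = list(
                              correlation_group = "amblyopic",
                              correlation_x = "axial_length_mm",
                              welch = TRUE),
                            verbose = TRUE) {
  cfg <- structure(list(seed = seed, simulate = simulate, input = input,
                        segmentation = segmentation,
                        magnification = modifyList(
                          list(enabled = TRUE,
                               reference_axial_length = 23.95),
                          magnification),
                        stats = modifyList(
                          list(correlation_group = "amblyopic",
                               correlation_x = "axial_length_mm",
                               welch = TRUE),
                          stats),
                        verbose = isTRUE(verbose)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  fail <- function(path, msg) stop("invalid config at ", path, ": ", msg,
                                   call. = FALSE)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    fail("seed", "must be an integer")
  has_sim <- !is.null(cfg$simulate)
  has_input <- !is.null(cfg$input)
  if (has_sim == has_input)
    fail("simulate/input", "exactly one input source must be configured")
  if (has_sim) {
    n <- cfg$simulate$n_per_group
    if (is.null(n) || n < 1L)
      fail("simulate$n_per_group", "must be >= 1")
    rho <- cfg$simulate$paired_eye_correlation %||% 0
    if (abs(rho) > 1)
      fail("simulate$paired_eye_correlation", "must be in [-1, 1]")
  } else {
    if (is.null(cfg$input$scans) || is.null(cfg$input$cohort_csv))
      fail("input", "needs both 'scans' and 'cohort_csv'")
  }
  ral <- cfg$magnification$reference_axial_length
  if (!is.null(ral) && ral <= 1.82)
    fail("magnification$reference_axial_length", "must exceed 1.82 mm")
  do.call(seg_config, cfg$segmentation) # validates, error carries fields
  invisible(cfg)
}

## Build the two phantom specs (horizontal + vertical meridian) of one eye
## from its drawn regional thickness measurements. Quadrant thicknesses are
## anchored at +/- eccentricity; central outer-layer thicknesses set the
## pit-floor geometry.
phantom_from_measurements <- function(row, phantom = list(), eye = "OD") {
  p <- modifyList(list(image_height = 496L, image_width = 512L,
                       axial_scale = 3.87, lateral_scale = 5.7,
                       noise_level = 0.1, blur_sigma = 1,
                       pit_radius = 180, eccentricity_um = 500), phantom)
  ax <- p$axial_scale
  th <- function(region, layer) row[[paste(region, layer, sep = "_")]]
  top <- round(0.3 * p$image_height)
  rows_for <- function(region) {
    top + cumsum(c(0, vapply(.LAYERS, th, 0, region = region))) / ax
  }
  central_outer <- vapply(.OUTER_LAYERS, th, 0, region = "central") / ax

  build <- function(meridian, left_region, right_region, nasal_side,
                    superior_side) {
    rows_l <- rows_for(left_region)
    rows_r <- rows_for(right_region)
    c_row <- mean(c(rows_l[5], rows_r[5]))
    phantom_spec(
      image_height = p$image_height, image_width = p$image_width,
      axial_scale = ax, lateral_scale = p$lateral_scale,
      eye = eye, meridian = meridian,
      base_boundary_rows = rows_l, base_boundary_rows_right = rows_r,
      central_outer_rows = c_row + cumsum(central_outer),
      side_anchor_um = p$eccentricity_um,
      pit_depth = (c_row - top) * ax, pit_radius = p$pit_radius,
      layer_intensities = p$layer_intensities %||%
        c(10, 170, 100, 50, 130, 40, 180, 80, 200, 70),
      noise_level = p$noise_level, blur_sigma = p$blur_sigma,
      axial_length_mm = row$axial_length_mm,
      nasal_side = nasal_side, superior_side = superior_side
    )
  }
  nasal_side <- if (eye == "OD") "low" else "high"
  list(
    horizontal = build("horizontal",
                       if (nasal_side == "low") "nasal" else "temporal",
                       if (nasal_side == "low") "temporal" else "nasal",
                       nasal_side, "low"),
    vertical = build("vertical", "superior", "inferior", nasal_side, "low")
  )
}

measured_to_wide <- function(long, cohort) {
  key <- paste(long$region, long$layer, sep = "_")
  ids <- unique(long[, c("subject", "group")])
  wide <- ids
  for (m in unique(key)) {
    sel <- key == m
    idx <- match(paste(wide$subject, wide$group),
                 paste(long$subject[sel], long$group[sel]))
    wide[[m]] <- long$thickness_um[sel][idx]
  }
  base_idx <- match(paste(wide$subject, wide$group),
                    paste(cohort$subject, cohort$group))
  for (v in c("age", "sex", "se_d", "axial_length_mm", "va_logmar")) {
    if (v %in% names(cohort)) wide[[v]] <- cohort[[v]][base_idx]
  }
  attr(wide, "schema_version") <- .SCHEMA_VERSION
  class(wide) <- c("oct_cohort", "data.frame")
  wide
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) B-scans and a cohort, segment every scan, convert to
#' magnification-corrected thickness profiles, sample the fovea, and run
#' the group-comparison stage. Writes `cohort.csv`, `boundaries.csv`,
#' `thickness.csv`, `report.csv`, `correlations.csv` and
#' `run_report.json` to `out_dir`. Deterministic under a fixed seed:
#' re-running with identical config produces byte-identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return An object of class `run_report`: per-stage record counts,
#'   collected warnings, output manifest, config echo and package version.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  segcfg <- do.call(seg_config, config$segmentation)
  info <- function(...) if (config$verbose) message("[foveaseg] ", ...)
  warns <- character(0)
  stage <- function(name, id, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed",
             if (!is.null(id)) paste0(" for ", id), ": ",
             conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, paste0(name, if (!is.null(id)) paste0(" [", id, "]"),
                                  ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  with_opt_seed(config$seed, {
    ## ---- acquire stage ----
    if (!is.null(config$simulate)) {
      info("simulate: generating cohort (n = ",
           config$simulate$n_per_group, " per group)")
      sim <- config$simulate
      cs_args <- sim[intersect(names(sim),
                               names(formals(cohort_spec)))]
      cs_args$n_per_group <- sim$n_per_group
      cohort <- stage("simulate", NULL,
                      generate_cohort(do.call(cohort_spec, cs_args)))
      scans <- list()
      for (i in seq_len(nrow(cohort))) {
        row <- cohort[i, ]
        id <- paste0(row$subject, "_", row$group)
        eye <- if (row$group == "fellow") "OS" else "OD"
        specs <- stage("simulate", id,
                       phantom_from_measurements(row, sim$phantom %||% list(),
                                                 eye = eye))
        scans[[id]] <- lapply(specs, function(s) {
          ph <- generate_bscan(s)
          ph$scan
        })
      }
    } else {
      info("load: reading scans and cohort from disk")
      cohort <- stage("load", config$input$cohort_csv,
                      read_cohort(config$input$cohort_csv))
      sc <- config$input$scans
      scans <- list()
      for (i in seq_len(nrow(sc))) {
        id <- paste0(sc$subject[i], "_", sc$group[i])
        if (is.null(scans[[id]])) scans[[id]] <- list()
        scans[[id]][[sc$meridian[i]]] <-
          stage("load", sc$image[i], read_bscan(sc$image[i]))
      }
    }

    ## ---- segment + measure stages ----
    info("segment/measure: ", length(scans), " eyes, 2 meridians each")
    ref_al <- config$magnification$reference_axial_length
    boundary_rows <- list()
    long <- list()
    for (id in names(scans)) {
      sg <- strsplit(id, "_")[[1]]
      pair <- scans[[id]]
      profiles <- list()
      for (mer in c("horizontal", "vertical")) {
        scan <- pair[[mer]]
        if (is.null(scan)) stop("stage 'segment' failed for ", id,
                                ": missing ", mer, " scan", call. = FALSE)
        bs <- stage("segment", paste0(id, " (", mer, ")"),
                    segment_layers(scan, segcfg))
        boundary_rows[[paste0(id, "_", mer)]] <-
          data.frame(scan = paste0(id, "_", mer),
                     column = seq_len(ncol(bs$rows)), t(bs$rows))
        lat <- scan$meta$lateral_scale
        if (isTRUE(config$magnification$enabled))
          lat <- corrected_lateral_scale(lat, scan$meta$axial_length_mm,
                                         ref_al)
        profiles[[mer]] <- boundaries_to_thickness(bs, lateral_scale = lat)
      }
      fs <- stage("measure", id,
                  sample_fovea(profiles$horizontal, profiles$vertical))
      long[[id]] <- as.data.frame(fs, subject = sg[1], group = sg[2])
    }
    long <- do.call(rbind, long)
    rownames(long) <- NULL

    ## ---- compare stage ----
    info("compare: ANCOVA / Bonferroni / correlations")
    wide <- measured_to_wide(long, cohort)
    report <- stage("compare", NULL, layer_report(wide))
    skipped <- 0L
    cors <- do.call(rbind, lapply(thickness_columns(wide), function(m) {
      cr <- tryCatch(
        correlate_thickness(wide, config$stats$correlation_x, m,
                            config$stats$correlation_group),
        error = function(e) {
          warns <<- c(warns, paste0("compare [", m, "]: correlation skipped: ",
                                    conditionMessage(e)))
          skipped <<- skipped + 1L
          NULL
        })
      if (is.null(cr)) return(NULL)
      data.frame(x = cr$x, outcome = m, r = cr$r, p = cr$p, n = cr$n,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(cors))
      cors <- data.frame(x = character(0), outcome = character(0),
                         r = numeric(0), p = numeric(0), n = integer(0))
    rownames(cors) <- NULL

    ## ---- write stage ----
    paths <- c(
      cohort = file.path(out_dir, "cohort.csv"),
      boundaries = file.path(out_dir, "boundaries.csv"),
      thickness = file.path(out_dir, "thickness.csv"),
      report = file.path(out_dir, "report.csv"),
      correlations = file.path(out_dir, "correlations.csv"),
      run_report = file.path(out_dir, "run_report.json")
    )
    write_cohort(cohort, paths[["cohort"]])
    bdf <- do.call(rbind, boundary_rows)
    rownames(bdf) <- NULL
    write_csv_schema(bdf, paths[["boundaries"]], "boundary_set_long")
    write_thickness_long(long, paths[["thickness"]])
    write_report(report, paths[["report"]])
    write_csv_schema(cors, paths[["correlations"]], "correlations")

    rep <- structure(list(
      counts = list(eyes = length(scans), scans = 2L * length(scans),
                    cohort_rows = nrow(cohort),
                    thickness_rows = nrow(long),
                    outcomes = nrow(report), skipped = skipped),
      warnings = warns,
      manifest = unname(paths),
      config = unclass(config),
      version = as.character(packageVersion("foveaseg"))
    ), class = "run_report")
    jsonlite::write_json(unclass(rep[c("counts", "warnings", "manifest",
                                       "version")]),
                         paths[["run_report"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
    info("done: ", length(paths), " files in ", out_dir)
    rep
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> foveaseg", x$version, "\n")
  cat(sprintf("  eyes %d, scans %d, thickness rows %d, outcomes %d, skipped %d\n",
              x$counts$eyes, x$counts$scans, x$counts$thickness_rows,
              x$counts$outcomes, x$counts$skipped))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  cat("  files:\n", paste0("    ", x$manifest, "\n"), sep = "")
  invisible(x)
}
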