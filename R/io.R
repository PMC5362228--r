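## File round-tripping: images + sidecars, schema-versioned CSVs -------------

schema_header <- function(id) {
  sprintf("# foveaseg-schema: %s v%s", id, .SCHEMA_VERSION)
}

write_csv_schema <- function(df, path, id) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(schema_header(id), con)
  write.table(df, con, sep = ",", dec = ".", row.names = FALSE,
              qmethod = "double")
  invisible(path)
}

read_csv_schema <- function(path, id, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# foveaseg-schema:"))
    warning("no schema header in ", path, "; attempting to parse anyway")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema mismatch in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Write / read a B-scan image with its metadata sidecar
#'
#' The image is written as 16-bit grayscale TIFF (`.tif`/`.tiff`) or PNG
#' (`.png`), intensities scaled from the internal 0--255 range to `[0, 1]`
#' and clipped. The JSON sidecar carries the acquisition metadata (eye,
#' meridian, pixel scales, axial length, column-direction conventions,
#' seed) plus a schema version.
#'
#' @param scan An [oct_scan()].
#' @param image_path Output image path; format chosen by extension.
#' @param sidecar_path JSON sidecar path; default `image_path` with a
#'   `.json` extension.
#' @return `image_path`, invisibly (`write_bscan`); an `oct_scan`
#'   (`read_bscan`).
#' @export
write_bscan <- function(scan, image_path, sidecar_path = NULL) {
  stopifnot(inherits(scan, "oct_scan"))
  sidecar_path <- sidecar_path %||% paste0(sub("\\.[^.]+$", "", image_path),
                                           ".json")
  im <- scan$image / 255
  im[im < 0] <- 0
  im[im > 1] <- 1
  ext <- tolower(sub("^.*\\.", "", image_path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(im, image_path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(im, image_path)
  } else stop("unsupported image format: .", ext)
  meta <- scan$meta
  meta$schema <- paste0("foveaseg-bscan-v", .SCHEMA_VERSION)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(image_path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(image_path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||% paste0(sub("\\.[^.]+$", "", image_path),
                                           ".json")
  ext <- tolower(sub("^.*\\.", "", image_path))
  im <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(image_path)
        else if (ext == "png") png::readPNG(image_path)
        else stop("unsupported image format: .", ext)
  if (length(dim(im)) == 3L) im <- im[, , 1]
  meta <- list()
  if (file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    meta$schema <- NULL
  }
  oct_scan(im * 255, meta)
}

#' Write / read boundary sets, thickness tables, cohorts and reports
#'
#' CSV round-tripping with a schema-version comment header, dot-decimal and
#' UTF-8 regardless of locale. `read_*` validates the column schema and
#' names any missing column.
#'
#' @param x Object to write (see individual functions).
#' @param path CSV path.
#' @param meta Optional metadata for reconstructed objects.
#' @return The written path (writers, invisibly) or the parsed object
#'   (readers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_boundaries <- function(x, path) {
  stopifnot(inherits(x, "boundary_set"))
  df <- data.frame(column = seq_len(ncol(x$rows)), t(x$rows))
  write_csv_schema(df, path, "boundary_set")
}

#' @rdname table_io
#' @export
read_boundaries <- function(path, meta = list()) {
  df <- read_csv_schema(path, "boundary_set", c("column", .BOUNDS))
  m <- t(as.matrix(df[order(df$column), .BOUNDS]))
  dimnames(m) <- list(.BOUNDS, NULL)
  boundary_set(m, meta = meta)
}

#' @rdname table_io
#' @export
write_thickness_long <- function(x, path) {
  need <- c("subject", "group", "region", "layer", "thickness_um")
  stopifnot(all(need %in% names(x)))
  write_csv_schema(x[, need], path, "thickness_long")
}

#' @rdname table_io
#' @export
read_thickness_long <- function(path) {
  read_csv_schema(path, "thickness_long",
                  c("subject", "group", "region", "layer", "thickness_um"))
}

#' @rdname table_io
#' @export
write_cohort <- function(x, path) {
  write_csv_schema(as.data.frame(x), path, "cohort")
}

#' @rdname table_io
#' @export
read_cohort <- function(path) {
  df <- read_csv_schema(path, "cohort",
                        c("subject", "group", "age", "sex"))
  attr(df, "schema_version") <- .SCHEMA_VERSION
  class(df) <- c("oct_cohort", "data.frame")
  df
}

#' @rdname table_io
#' @export
write_report <- function(x, path) {
  write_csv_schema(as.data.frame(x), path, "layer_report")
}

#' @rdname table_io
#' @export
read_report <- function(path) {
  df <- read_csv_schema(path, "layer_report",
                        c("region", "layer", "amblyopic_mean",
                          "fellow_mean", "control_mean"))
  class(df) <- c("layer_report", "data.frame")
  df
}

#' Write a segmentation overlay image
#'
#' Renders the scan in grayscale with the boundary curves burned in, as an
#' 8-bit RGB PNG.
#'
#' @param scan An [oct_scan()].
#' @param boundaries A `boundary_set`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(scan, boundaries, path) {
  im <- scan$image / 255
  im[im < 0] <- 0
  im[im > 1] <- 1
  H <- nrow(im); W <- ncol(im)
  rgb <- array(im, dim = c(H, W, 3L))
  b <- round(as.matrix(boundaries))
  for (k in 1:9) {
    r <- pmin(H, pmax(1L, b[k, ]))
    idx <- cbind(r, seq_len(W))
    rgb[cbind(idx, 1L)] <- 1
    rgb[cbind(idx, 2L)] <- 0
    rgb[cbind(idx, 3L)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
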