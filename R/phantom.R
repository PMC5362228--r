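## Synthetic B-scan phantoms with known ground truth --------------------------

#' Specify a synthetic foveal B-scan phantom
#'
#' Builds the parameter object consumed by [generate_bscan()]. The phantom is
#' a stack of ten intensity compartments (vitreous, the eight intra-retinal
#' layers, choroid) separated by nine boundaries. The periphery is
#' piecewise-flat; a Gaussian foveal pit pulls boundaries B1--B5 down to a
#' common pit-floor row so the four inner layers (NFL, GCL+IPL, INL, OPL)
#' vanish at the pit center, as they do anatomically. Rendering applies
#' Gaussian blur and multiplicative speckle.
#'
#' Default boundary spacing reproduces the reference control-eye nasal layer
#' thicknesses of [foveal_thickness_reference()], and the default pit depth
#' is set so the central total thickness equals the reference control
#' central total.
#'
#' @param image_height,image_width Image size in pixels (depth x lateral).
#' @param axial_scale,lateral_scale Pixel pitch in micrometers per pixel.
#' @param eye `"OD"` or `"OS"`.
#' @param meridian `"horizontal"` or `"vertical"`.
#' @param base_boundary_rows Nine strictly increasing reference row positions
#'   (pixels, sub-pixel allowed) for the flat periphery on the low-column
#'   side. Default derives from the reference control nasal thicknesses.
#' @param base_boundary_rows_right Optional nine rows for the high-column
#'   side (defaults to `base_boundary_rows`; rows vary linearly between the
#'   two side anchors, allowing nasal/temporal asymmetry).
#' @param central_outer_rows Optional rows of B6--B9 at the pit center
#'   (length 4); when given, the outer boundaries interpolate linearly from
#'   each side anchor to these central values.
#' @param side_anchor_um Lateral distance from the pit center (micrometers)
#'   at which the side rows apply; rows are flat beyond the anchors.
#' @param pit_depth Pit depth in micrometers: how far below the peripheral
#'   B1 row the pit floor lies. `0` disables the pit entirely.
#' @param pit_radius Gaussian sigma of the pit profile, micrometers.
#' @param pit_center_column Column of the pit center (pixels).
#' @param layer_intensities Ten mean gray levels (vitreous, 8 layers,
#'   choroid) on a 0--255 scale.
#' @param min_contrast Minimum absolute gray-level difference required
#'   between adjacent compartments, so every boundary has a defined gradient
#'   polarity.
#' @param noise_level Speckle contrast: coefficient of variation of the
#'   multiplicative mean-1 gamma noise, in `[0, 1)`.
#' @param blur_sigma Gaussian blur sigma in pixels (applied before speckle).
#' @param axial_length_mm Simulated axial length carried in the metadata
#'   sidecar (input to the Bennett magnification correction downstream).
#' @param nasal_side For horizontal scans: which column side of the image is
#'   nasal retina, `"low"` or `"high"`. Defaults to `"low"` for OD and
#'   `"high"` for OS.
#' @param superior_side For vertical scans: which column side is superior.
#'   Default `"low"`.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output. `NULL` uses the current RNG state.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_bscan()]
#' @export
phantom_spec <- function(image_height = 496L,
                         image_width = 512L,
                         axial_scale = 3.87,
                         lateral_scale = 5.7,
                         eye = c("OD", "OS"),
                         meridian = c("horizontal", "vertical"),
                         base_boundary_rows = NULL,
                         base_boundary_rows_right = NULL,
                         central_outer_rows = NULL,
                         side_anchor_um = 500,
                         pit_depth = NULL,
                         pit_radius = 180,
                         pit_center_column = NULL,
                         layer_intensities = c(10, 170, 100, 50, 130,
                                               40, 180, 80, 200, 70),
                         min_contrast = 20,
                         noise_level = 0.1,
                         blur_sigma = 1,
                         axial_length_mm = 23.95,
                         nasal_side = NULL,
                         superior_side = "low",
                         seed = NULL) {
  eye <- match.arg(eye)
  meridian <- match.arg(meridian)
  if (is.null(base_boundary_rows)) {
    base_boundary_rows <- default_base_rows(axial_scale, image_height)
  }
  if (is.null(base_boundary_rows_right)) {
    base_boundary_rows_right <- base_boundary_rows
  }
  if (is.null(pit_depth)) {
    ## depth that brings the central total down to the reference control
    ## central total thickness
    ref <- foveal_thickness_reference()
    target <- ref$mean[ref$region == "central" & ref$layer == "total" &
                         ref$group == "control"]
    b1 <- mean(c(base_boundary_rows[1], base_boundary_rows_right[1]))
    b9 <- mean(c(base_boundary_rows[9], base_boundary_rows_right[9]))
    pit_depth <- (b9 - b1) * axial_scale - target
  }
  if (is.null(pit_center_column)) pit_center_column <- image_width / 2
  if (is.null(nasal_side)) nasal_side <- if (eye == "OD") "low" else "high"

  spec <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    axial_scale = axial_scale, lateral_scale = lateral_scale,
    eye = eye, meridian = meridian,
    base_boundary_rows = as.numeric(base_boundary_rows),
    base_boundary_rows_right = as.numeric(base_boundary_rows_right),
    central_outer_rows = central_outer_rows,
    side_anchor_um = side_anchor_um,
    pit_depth = pit_depth, pit_radius = pit_radius,
    pit_center_column = pit_center_column,
    layer_intensities = as.numeric(layer_intensities),
    min_contrast = min_contrast,
    noise_level = noise_level, blur_sigma = blur_sigma,
    axial_length_mm = axial_length_mm,
    nasal_side = match.arg(nasal_side, c("low", "high")),
    superior_side = match.arg(superior_side, c("low", "high")),
    seed = seed
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

## Peripheral boundary rows spaced like the reference control nasal layer
## thicknesses, with the ILM placed at 30% of the image height.
default_base_rows <- function(axial_scale, image_height) {
  ref <- foveal_thickness_reference()
  th <- ref[ref$region == "nasal" & ref$group == "control" &
              ref$layer != "total", ]
  th <- th$mean[match(.LAYERS, th$layer)]
  top <- round(0.3 * image_height)
  top + cumsum(c(0, th)) / axial_scale
}

validate_phantom_spec <- function(spec) {
  H <- spec$image_height; W <- spec$image_width
  if (H < 3L || W < 3L) stop("image must be at least 3 x 3 pixels")
  if (spec$axial_scale <= 0 || spec$lateral_scale <= 0)
    stop("pixel scales must be positive")
  for (rows in list(spec$base_boundary_rows, spec$base_boundary_rows_right)) {
    if (length(rows) != 9L) stop("base_boundary_rows must have length 9")
    if (any(diff(rows) <= 0))
      stop("base_boundary_rows must be strictly increasing")
    if (rows[1] < 1 || rows[9] > H)
      stop("base_boundary_rows must lie within the image")
  }
  if (!is.null(spec$central_outer_rows) &&
      length(spec$central_outer_rows) != 4L)
    stop("central_outer_rows must give rows for B6..B9 (length 4)")
  ints <- spec$layer_intensities
  if (length(ints) != 10L) stop("layer_intensities must have length 10")
  if (any(abs(diff(ints)) < spec$min_contrast))
    stop("adjacent compartments must differ by at least min_contrast (",
         spec$min_contrast, " gray levels)")
  if (spec$noise_level < 0 || spec$noise_level >= 1)
    stop("noise_level must be in [0, 1)")
  if (spec$blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (spec$pit_depth < 0) stop("pit_depth must be >= 0")
  if (spec$pit_radius <= 0) stop("pit_radius must be positive")
  ## pit feasibility: the pit floor must stay above B6 and inside the image
  if (spec$pit_depth > 0) {
    b <- phantom_boundary_rows(spec, check = FALSE)
    if (any(b < 1 | b > H))
      stop("pit_depth/pit_radius push a boundary outside the image")
    if (any(diff_rows(b) < -1e-9))
      stop("pit_depth/pit_radius violate the boundary ordering ",
           "(pit floor must stay above B6)")
  }
  invisible(spec)
}

diff_rows <- function(b) b[-1, , drop = FALSE] - b[-nrow(b), , drop = FALSE]

## Ground-truth boundary rows (9 x width), sub-pixel, in row coordinates
## where pixel centers sit at integer rows 1..H.
phantom_boundary_rows <- function(spec, check = TRUE) {
  W <- spec$image_width
  x <- seq_len(W)
  ctr <- spec$pit_center_column
  a_px <- spec$side_anchor_um / spec$lateral_scale
  xl <- ctr - a_px; xr <- ctr + a_px
  L <- spec$base_boundary_rows
  R <- spec$base_boundary_rows_right
  tfrac <- pmin(1, pmax(0, (x - xl) / (xr - xl)))
  base <- matrix(NA_real_, 9L, W, dimnames = list(.BOUNDS, NULL))
  for (k in 1:9) base[k, ] <- L[k] + (R[k] - L[k]) * tfrac
  if (!is.null(spec$central_outer_rows)) {
    tl <- pmin(1, pmax(0, (x - xl) / (ctr - xl)))
    tr <- pmin(1, pmax(0, (xr - x) / (xr - ctr)))
    for (k in 6:9) {
      ck <- spec$central_outer_rows[k - 5L]
      base[k, ] <- ifelse(x <= ctr,
                          L[k] + (ck - L[k]) * tl,
                          R[k] + (ck - R[k]) * tr)
    }
  }
  if (spec$pit_depth > 0) {
    sig <- spec$pit_radius / spec$lateral_scale
    p <- exp(-((x - ctr)^2) / (2 * sig^2))
    floor_row <- mean(c(L[1], R[1])) + spec$pit_depth / spec$axial_scale
    for (k in 1:5) base[k, ] <- base[k, ] * (1 - p) + floor_row * p
  }
  if (check && any(diff_rows(base) < -1e-9))
    stop("phantom boundaries are not ordered; check pit and anchor settings")
  base
}

#' Generate a synthetic B-scan with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: compartments are
#' filled with their mean intensities using anti-aliased (partial-volume)
#' coverage, blurred with a Gaussian of `blur_sigma`, then multiplied by
#' mean-1 gamma speckle whose coefficient of variation is `noise_level`.
#' Identical spec + seed produces bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `scan` (an `oct_scan`: intensity matrix
#'   plus acquisition metadata) and `truth` (a `boundary_set` of the nine
#'   sub-pixel ground-truth boundary rows).
#' @export
#' @examples
#' ph <- generate_bscan(phantom_spec(noise_level = 0, seed = 1))
#' dim(ph$scan$image)
#' ph$truth
generate_bscan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  truth_rows <- phantom_boundary_rows(spec)
  img <- with_opt_seed(spec$seed, {
    im <- render_compartments(truth_rows, spec$image_height,
                              spec$layer_intensities)
    if (spec$blur_sigma > 0) im <- gaussian_blur(im, spec$blur_sigma)
    if (spec$noise_level > 0) {
      k <- 1 / spec$noise_level^2
      im <- im * matrix(rgamma(length(im), shape = k, rate = k),
                        nrow = nrow(im))
    }
    im
  })
  meta <- list(
    eye = spec$eye, meridian = spec$meridian,
    axial_scale = spec$axial_scale, lateral_scale = spec$lateral_scale,
    axial_length_mm = spec$axial_length_mm,
    nasal_side = spec$nasal_side, superior_side = spec$superior_side,
    seed = spec$seed
  )
  list(scan = oct_scan(img, meta),
       truth = boundary_set(truth_rows, meta, source = "ground_truth"))
}

## Anti-aliased rendering: pixel (r, x) takes the coverage-weighted mean of
## the compartment intensities overlapping [r - 0.5, r + 0.5].
render_compartments <- function(brows, H, intensities) {
  W <- ncol(brows)
  b <- rbind(rep(-1e6, W), brows, rep(1e6, W)) # 11 x W compartment edges
  r <- seq_len(H)
  img <- matrix(0, H, W)
  for (k in 1:10) {
    topM <- matrix(b[k, ], H, W, byrow = TRUE)
    botM <- matrix(b[k + 1L, ], H, W, byrow = TRUE)
    cov <- pmin(botM, r + 0.5) - pmax(topM, r - 0.5)
    cov[cov < 0] <- 0
    img <- img + intensities[k] * cov
  }
  img
}

gaussian_blur <- function(im, sigma) {
  out <- EBImage::gblur(im, sigma = sigma)
  matrix(as.numeric(out), nrow = nrow(im))
}

## oct_scan -------------------------------------------------------------------

#' Construct an OCT B-scan object
#'
#' @param image Numeric intensity matrix (rows = depth, columns = lateral).
#' @param meta List of acquisition metadata: `eye`, `meridian`,
#'   `axial_scale`, `lateral_scale` (micrometers/pixel), `axial_length_mm`,
#'   `nasal_side`/`superior_side` column-direction conventions, `seed`.
#' @return An object of class `oct_scan`.
#' @export
oct_scan <- function(image, meta = list()) {
  stopifnot(is.matrix(image), is.numeric(image))
  structure(list(image = image, meta = meta), class = "oct_scan")
}

#' @export
print.oct_scan <- function(x, ...) {
  cat(sprintf("<oct_scan> %d x %d px (%s, %s scan), %.2f x %.2f um/px\n",
              nrow(x$image), ncol(x$image),
              x$meta$eye %||% "?", x$meta$meridian %||% "?",
              x$meta$axial_scale %||% NA, x$meta$lateral_scale %||% NA))
  invisible(x)
}

#' @export
plot.oct_scan <- function(x, boundaries = NULL, ...) {
  im <- x$image
  im <- (im - min(im)) / max(1e-12, diff(range(im)))
  graphics::image(x = seq_len(ncol(im)), y = seq_len(nrow(im)),
                  z = t(im[nrow(im):1, ]), col = grDevices::gray.colors(256),
                  xlab = "column (px)", ylab = "row (px)", useRaster = TRUE,
                  ...)
  if (!is.null(boundaries)) {
    b <- as.matrix(boundaries)
    for (k in seq_len(nrow(b))) {
      graphics::lines(seq_len(ncol(b)), nrow(im) + 1 - b[k, ], col = "red")
    }
  }
  invisible(x)
}

## boundary_set ---------------------------------------------------------------

#' Construct a set of nine ordered boundary curves
#'
#' @param rows 9 x width numeric matrix of sub-pixel row positions, one row
#'   per boundary B1..B9, ordered `B1 <= ... <= B9` at every column
#'   (equality allowed where layers vanish at the foveal pit).
#' @param meta Acquisition metadata list (see [oct_scan()]).
#' @param source `"ground_truth"` or `"estimated"`.
#' @param costs Optional named numeric path costs per boundary.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(rows, meta = list(), source = "estimated",
                         costs = NULL) {
  stopifnot(is.matrix(rows), nrow(rows) == 9L)
  rownames(rows) <- .BOUNDS
  if (any(diff_rows(rows) < -1e-6))
    stop("boundary rows violate the ordering B1 <= ... <= B9")
  structure(list(rows = rows, meta = meta, source = source, costs = costs),
            class = "boundary_set")
}

#' @export
as.matrix.boundary_set <- function(x, ...) x$rows

#' @export
print.boundary_set <- function(x, ...) {
  rng <- apply(x$rows, 1, range)
  cat(sprintf("<boundary_set> 9 boundaries x %d columns (%s)\n",
              ncol(x$rows), x$source))
  cat(sprintf("  %s: rows %.1f-%.1f\n", rownames(x$rows), rng[1, ], rng[2, ]),
      sep = "")
  invisible(x)
}
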