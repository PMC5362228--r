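## Graph shortest-path boundary segmentation ---------------------------------

#' Compute polarity-split vertical gradient maps
#'
#' Smooths the image with a Gaussian of `smoothing_sigma`, takes the
#' vertical central difference (positive downward), and splits it into a
#' dark-to-light map (positive part) and a light-to-dark map (negative
#' part), each min-max normalized to `[0, 1]` (a constant image yields
#' all-zero maps). These are the node-affinity maps of the boundary graphs.
#'
#' @param image Numeric intensity matrix, at least 3 x 3.
#' @param smoothing_sigma Gaussian sigma in pixels; 0 disables smoothing.
#' @return An object of class `gradient_maps`: list with matrices
#'   `dark_to_light`, `light_to_dark` and the image `dim`.
#' @export
compute_gradient_maps <- function(image, smoothing_sigma = 0.8) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3 x 3 pixels")
  im <- if (smoothing_sigma > 0) gaussian_blur(image, smoothing_sigma) else image
  H <- nrow(im)
  d <- matrix(0, H, ncol(im))
  d[2:(H - 1L), ] <- (im[3:H, ] - im[1:(H - 2L), ]) / 2
  norm01 <- function(m) {
    mx <- max(m)
    if (mx > 0) m / mx else m * 0
  }
  structure(list(dark_to_light = norm01(pmax(d, 0)),
                 light_to_dark = norm01(pmax(-d, 0)),
                 dim = dim(image)),
            class = "gradient_maps")
}

#' Per-column search region
#'
#' @param row_min,row_max Integer vectors (one entry per column) giving the
#'   inclusive band within which a boundary may lie.
#' @param n_rows Image height, for validation.
#' @return An object of class `search_region`.
#' @export
search_region <- function(row_min, row_max, n_rows) {
  stopifnot(length(row_min) == length(row_max))
  if (any(row_min < 1L) || any(row_max > n_rows) || any(row_min > row_max))
    stop("search region must satisfy 1 <= row_min <= row_max <= image height")
  structure(list(row_min = as.integer(row_min),
                 row_max = as.integer(row_max),
                 n_rows = as.integer(n_rows)),
            class = "search_region")
}

#' Segmentation configuration
#'
#' Operator settings of the sequential shortest-path protocol. The defaults
#' are matched to the default phantom intensity scheme: boundaries are
#' detected highest-contrast first, each with the gradient polarity its
#' intensity step produces.
#'
#' @param order Detection order; a permutation of `B1..B9`.
#' @param polarity Named character vector mapping each boundary to
#'   `"dark_to_light"` or `"light_to_dark"`.
#' @param margin_um Exclusion margin (micrometers) applied between a new
#'   search region and already-accepted boundaries *of the same polarity*,
#'   preventing a weaker boundary from locking onto a stronger neighbour's
#'   edge. Opposite-polarity pairs get margin 0 so the inner boundaries can
#'   genuinely coalesce at the foveal pit.
#' @param w_min Node-weight floor added to `1 - g`.
#' @param max_jump Maximum vertical step between adjacent columns, pixels.
#' @param smoothing_sigma Gaussian sigma for the gradient maps, pixels.
#' @param step_penalty Cost added per pixel of vertical step on each edge; a
#'   small deterministic tie-break that keeps paths straight where the
#'   gradient is uninformative (e.g. inside the pit).
#' @param min_retina_um Anatomical minimum total retinal thickness
#'   (micrometers): once Bruch's membrane (B9) is accepted, the ILM (B1) is
#'   searched at least this far above it (and vice versa), so a locally
#'   weak vitreoretinal edge (thin NFL) cannot lock onto the outer-retinal
#'   bands.
#' @param subpixel Refine integer paths by a per-column parabolic fit of the
#'   gradient over +/-1 pixel.
#' @param flatten Pre-flatten the image by aligning columns to a provisional
#'   Bruch's membrane before segmenting (for steeply curved inputs).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(order = c("B9", "B1", "B6", "B8", "B7",
                                 "B5", "B2", "B4", "B3"),
                       polarity = c(B1 = "dark_to_light",
                                    B2 = "light_to_dark",
                                    B3 = "light_to_dark",
                                    B4 = "dark_to_light",
                                    B5 = "light_to_dark",
                                    B6 = "dark_to_light",
                                    B7 = "light_to_dark",
                                    B8 = "dark_to_light",
                                    B9 = "light_to_dark"),
                       margin_um = 8,
                       w_min = 1e-5,
                       max_jump = 1L,
                       smoothing_sigma = 0.8,
                       step_penalty = 1e-3,
                       min_retina_um = 100,
                       subpixel = TRUE,
                       flatten = FALSE) {
  if (!setequal(order, .BOUNDS) || length(order) != 9L)
    stop("order must be a permutation of B1..B9")
  if (!all(.BOUNDS %in% names(polarity)))
    stop("polarity must name every boundary B1..B9")
  if (!all(polarity %in% c("dark_to_light", "light_to_dark")))
    stop("polarity values must be 'dark_to_light' or 'light_to_dark'")
  if (margin_um < 0 || w_min <= 0 || max_jump < 1L || step_penalty < 0 ||
      min_retina_um < 0)
    stop("invalid seg_config numeric settings")
  structure(list(order = order, polarity = polarity[.BOUNDS],
                 margin_um = margin_um, w_min = w_min,
                 max_jump = as.integer(max_jump),
                 smoothing_sigma = smoothing_sigma,
                 step_penalty = step_penalty,
                 min_retina_um = min_retina_um,
                 subpixel = isTRUE(subpixel), flatten = isTRUE(flatten)),
            class = "seg_config")
}

shift_vec <- function(v, s) {
  n <- length(v)
  if (s == 0L) return(v)
  if (s > 0L) c(rep(Inf, s), v[seq_len(n - s)])
  else c(v[(1L - s):n], rep(Inf, -s))
}

#' Minimum-cost boundary path on a gradient map
#'
#' Finds the minimum-cost left-to-right path through the selected gradient
#' map. Node weight is `w = 1 - g + w_min`; the cost of an edge between
#' nodes `a`, `b` in adjacent columns is
#' `w(a) + w(b) + step_penalty * |row(a) - row(b)|`, vertical steps are
#' limited to `max_jump` pixels, and one virtual zero-weight column is
#' appended on each side so the endpoints are data-driven. The reported
#' cost is the sum of edge costs, including the two virtual edges.
#'
#' @param maps A [compute_gradient_maps()] result.
#' @param polarity `"dark_to_light"` or `"light_to_dark"`.
#' @param region A [search_region()]; the path is restricted to its band.
#' @param config A [seg_config()].
#' @return An object of class `boundary_path`: list with `rows` (integer
#'   row per column), `polarity`, `cost`.
#' @export
shortest_boundary <- function(maps, polarity = c("dark_to_light",
                                                 "light_to_dark"),
                              region, config = seg_config()) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(maps, "gradient_maps"), inherits(region, "search_region"))
  g <- maps[[polarity]]
  H <- nrow(g); W <- ncol(g)
  if (length(region$row_min) != W)
    stop("search region width does not match the image")
  J <- config$max_jump
  lam <- config$step_penalty

  ## band feasibility: consecutive columns must be reachable within max_jump
  if (W > 1L) {
    gap <- pmax(region$row_min[-1L] - region$row_max[-W] - J,
                region$row_min[-W] - region$row_max[-1L] - J)
    bad <- which(gap > 0L)
    if (length(bad))
      stop(sprintf(
        "infeasible search region: column %d is not reachable from column %d within max_jump = %d",
        bad[1] + 1L, bad[1], J))
  }

  w <- 1 - g + config$w_min
  rows_idx <- seq_len(H)
  for (x in seq_len(W)) {
    out <- rows_idx < region$row_min[x] | rows_idx > region$row_max[x]
    if (any(out)) w[out, x] <- Inf
  }

  shifts <- c(0L, as.vector(rbind(-seq_len(J), seq_len(J)))) # 0, -1, 1, -2, 2, ...
  C <- 2 * w[, 1L]
  P <- matrix(0L, H, W)
  for (x in 2:W) {
    best <- rep(Inf, H)
    ptr <- integer(H)
    for (s in shifts) {
      cand <- shift_vec(C, s) + lam * abs(s)
      upd <- cand < best
      if (any(upd)) {
        best[upd] <- cand[upd]
        ptr[upd] <- s
      }
    }
    C <- 2 * w[, x] + best
    P[, x] <- ptr
  }
  r_end <- which.min(C)
  if (!is.finite(C[r_end])) stop("no feasible path through the search region")
  rows <- integer(W)
  rows[W] <- r_end
  for (x in W:2) rows[x - 1L] <- rows[x] - P[rows[x], x]
  structure(list(rows = rows, polarity = polarity, cost = C[r_end]),
            class = "boundary_path")
}

## Parabolic sub-pixel refinement of an integer path on its gradient map.
refine_subpixel <- function(rows, g) {
  H <- nrow(g); W <- ncol(g)
  out <- as.numeric(rows)
  ok <- rows > 1L & rows < H
  for (x in which(ok)) {
    r <- rows[x]
    y1 <- g[r - 1L, x]; y2 <- g[r, x]; y3 <- g[r + 1L, x]
    den <- y1 - 2 * y2 + y3
    if (den < -1e-12) {
      delta <- 0.5 * (y1 - y3) / den
      out[x] <- r + max(-0.5, min(0.5, delta))
    }
  }
  out
}

#' Segment the nine intra-retinal boundaries of a B-scan
#'
#' Executes the sequential shortest-path protocol: boundaries are detected
#' in `config$order`; after each detection the remaining search regions are
#' restricted to respect anatomical ordering, with a polarity-aware
#' exclusion margin around already-accepted boundaries. Where constraints
#' leave no room (the foveal pit, where the inner layers genuinely vanish)
#' the band collapses onto the accepted boundary above, and any residual
#' crossing after sub-pixel refinement is resolved by clamping, producing
#' zero-thickness columns rather than a failure.
#'
#' @param scan An [oct_scan()].
#' @param config A [seg_config()].
#' @return A `boundary_set` with nine estimated boundaries satisfying
#'   `B1 <= ... <= B9` at every column.
#' @export
#' @examples
#' ph <- generate_bscan(phantom_spec(noise_level = 0, seed = 1))
#' est <- segment_layers(ph$scan)
#' boundary_error(ph$truth, est)
segment_layers <- function(scan, config = seg_config()) {
  stopifnot(inherits(scan, "oct_scan"), inherits(config, "seg_config"))
  img <- scan$image
  H <- nrow(img); W <- ncol(img)
  axial <- scan$meta$axial_scale %||% 1
  margin_px <- config$margin_um / axial

  offset <- NULL
  if (config$flatten) {
    fl <- flatten_image(img, config)
    img <- fl$image
    offset <- fl$offset
  }
  maps <- compute_gradient_maps(img, config$smoothing_sigma)

  est <- list()
  for (nm in config$order) {
    i <- match(nm, .BOUNDS)
    pol <- config$polarity[[nm]]
    lower <- rep(1, W)
    upper <- rep(H, W)
    sep_px <- config$min_retina_um / axial
    for (nm2 in names(est)) {
      j <- match(nm2, .BOUNDS)
      m <- if (identical(pol, config$polarity[[nm2]])) margin_px else 0
      if (i == 1L && j == 9L) m <- max(m, sep_px)
      if (i == 9L && j == 1L) m <- max(m, sep_px)
      if (j < i) lower <- pmax(lower, est[[nm2]] + m)
      if (j > i) upper <- pmin(upper, est[[nm2]] - m)
    }
    rmin <- pmin(H, pmax(1L, ceiling(lower - 1e-9)))
    rmax <- pmin(H, pmax(1L, floor(upper + 1e-9)))
    ## relax the band edges to a slope of max_jump per column so the band is
    ## always traversable (accepted boundaries may jump at noise pixels);
    ## ordering is re-imposed by clamping below
    J <- config$max_jump
    if (W > 1L) {
      for (x in 2:W) rmin[x] <- min(rmin[x], rmin[x - 1L] + J)
      for (x in (W - 1L):1L) rmin[x] <- min(rmin[x], rmin[x + 1L] + J)
      for (x in 2:W) rmax[x] <- max(rmax[x], rmax[x - 1L] - J)
      for (x in (W - 1L):1L) rmax[x] <- max(rmax[x], rmax[x + 1L] - J)
    }
    bad <- rmin > rmax # pinched out: collapse onto the boundary above
    rmax[bad] <- rmin[bad]
    bp <- tryCatch(
      shortest_boundary(maps, pol, search_region(rmin, rmax, H), config),
      error = function(e) stop("while segmenting ", nm, ": ",
                               conditionMessage(e), call. = FALSE))
    r <- if (config$subpixel) refine_subpixel(bp$rows, maps[[pol]])
         else as.numeric(bp$rows)
    for (nm2 in names(est)) { # ordering enforcement by clamping
      j <- match(nm2, .BOUNDS)
      if (j < i) r <- pmax(r, est[[nm2]])
      if (j > i) r <- pmin(r, est[[nm2]])
    }
    est[[nm]] <- r
    attr(est, "costs") <- c(attr(est, "costs"), setNames(bp$cost, nm))
  }

  rows <- do.call(rbind, est[.BOUNDS])
  if (!is.null(offset)) rows <- rows + matrix(offset, 9L, W, byrow = TRUE)
  boundary_set(rows, scan$meta, source = "estimated",
               costs = attr(est, "costs"))
}

## Shift each column so a provisional Bruch's membrane is horizontal.
flatten_image <- function(img, config) {
  H <- nrow(img); W <- ncol(img)
  maps <- compute_gradient_maps(img, config$smoothing_sigma)
  b9 <- shortest_boundary(maps, config$polarity[["B9"]],
                          search_region(rep(1L, W), rep(H, W), H), config)
  target <- round(stats::median(b9$rows))
  offset <- b9$rows - target # true row = flattened row + offset
  out <- img
  for (x in seq_len(W)) {
    s <- offset[x]
    if (s == 0) next
    if (s > 0) out[, x] <- c(img[(s + 1):H, x], rep(img[H, x], s))
    else out[, x] <- c(rep(img[1, x], -s), img[1:(H + s), x])
  }
  list(image = out, offset = offset)
}

#' Boundary position error between two boundary sets
#'
#' Column-wise absolute differences per boundary, converted to micrometers.
#'
#' @param truth,estimate `boundary_set` objects over the same columns.
#' @param axial_scale Micrometers per pixel; defaults to the metadata of
#'   `truth`.
#' @return Data frame with one row per boundary: `boundary`, `mae_um`,
#'   `rmse_um`, `max_um`.
#' @export
boundary_error <- function(truth, estimate, axial_scale = NULL) {
  bt <- as.matrix(truth); be <- as.matrix(estimate)
  if (!identical(dim(bt), dim(be)))
    stop("boundary sets have mismatched widths")
  if (is.null(axial_scale))
    axial_scale <- truth$meta$axial_scale %||% 1
  d <- abs(be - bt) * axial_scale
  data.frame(boundary = .BOUNDS,
             mae_um = rowMeans(d),
             rmse_um = sqrt(rowMeans(d^2)),
             max_um = apply(d, 1, max),
             row.names = NULL, stringsAsFactors = FALSE)
}
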