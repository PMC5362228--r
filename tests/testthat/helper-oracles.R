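# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# Exhaustive enumeration of every feasible left-to-right path. Cost matches
# the package's definition: sum of edge costs with one virtual zero-weight
# column on each side, node weight w, optional per-edge step penalty.
brute_path_cost <- function(w, rmin = rep(1L, ncol(w)),
                            rmax = rep(nrow(w), ncol(w)),
                            J = 1L, lam = 0) {
  W <- ncol(w)
  best <- Inf
  rec <- function(x, r, cost) {
    cost <- cost + 2 * w[r, x]
    if (x == W) {
      if (cost < best) best <<- cost
      return(invisible(NULL))
    }
    lo <- max(rmin[x + 1L], r - J)
    hi <- min(rmax[x + 1L], r + J)
    if (lo > hi) return(invisible(NULL))
    for (r2 in lo:hi) rec(x + 1L, r2, cost + lam * abs(r2 - r))
  }
  for (r in rmin[1L]:rmax[1L]) rec(1L, r, 0)
  best
}

# ANCOVA by explicit normal equations (thickness ~ group + centered age +
# male indicator), with the group F from the residual-sum-of-squares drop.
ancova_oracle <- function(y, group, age, sexM) {
  X <- cbind(1, as.numeric(group == "fellow"),
             as.numeric(group == "control"), age - mean(age), sexM)
  b <- solve(t(X) %*% X, t(X) %*% y)
  rss1 <- sum((y - X %*% b)^2)
  X0 <- X[, c(1, 4, 5)]
  b0 <- solve(t(X0) %*% X0, t(X0) %*% y)
  rss0 <- sum((y - X0 %*% b0)^2)
  df2 <- length(y) - ncol(X)
  list(beta = as.numeric(b),
       F = ((rss0 - rss1) / 2) / (rss1 / df2),
       df = c(2, df2))
}

welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Small fast phantom used where full default size is unnecessary.
small_phantom_spec <- function(...) {
  phantom_spec(image_height = 320L, image_width = 360L, ...)
}

# Bare thickness_profile builder for foveal-center unit tests.
toy_profile <- function(total, inner = 0, meridian = "horizontal",
                        lateral_scale = 5.7, eye = "OD",
                        nasal_side = "low", superior_side = "low") {
  W <- length(total)
  layers <- matrix(0, 8, W, dimnames = list(layer_names(), NULL))
  layers["nfl", ] <- inner
  layers["hfl_onl", ] <- total - inner
  structure(list(layers = layers, total = total,
                 lateral_um = (seq_len(W) - 1) * lateral_scale,
                 axial_scale = 3.87, lateral_scale = lateral_scale,
                 eye = eye, meridian = meridian,
                 nasal_side = nasal_side, superior_side = superior_side),
            class = "thickness_profile")
}
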