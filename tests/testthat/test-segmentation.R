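test_that("a noiseless phantom is segmented to sub-pixel accuracy", {
  ph <- generate_bscan(phantom_spec(noise_level = 0, seed = 1))
  est <- segment_layers(ph$scan)
  expect_equal(nrow(as.matrix(est)), 9L)
  err_px <- rowMeans(abs(as.matrix(est) - as.matrix(ph$truth)))
  expect_true(all(err_px < 0.5))
})

test_that("segmentation always returns nine ordered boundaries across noise levels", {
  for (nl in c(0, 0.1, 0.25)) {
    ph <- generate_bscan(small_phantom_spec(noise_level = nl, seed = 7))
    est <- segment_layers(ph$scan)
    b <- as.matrix(est)
    expect_equal(nrow(b), 9L)
    expect_true(all(b[-1, ] - b[-9, ] >= -1e-9))
    th <- boundaries_to_thickness(est)
    expect_equal(nrow(th$layers), 8L)
  }
})

test_that("median boundary error is non-decreasing in speckle level", {
  med_mae <- sapply(c(0, 0.1, 0.2), function(nl) {
    median(sapply(1:5, function(s) {
      ph <- generate_bscan(small_phantom_spec(noise_level = nl, seed = s))
      mean(abs(as.matrix(segment_layers(ph$scan)) - as.matrix(ph$truth)))
    }))
  })
  expect_true(all(diff(med_mae) >= 0))
})

test_that("contrast inversion with swapped polarities reproduces the boundaries", {
  ph <- generate_bscan(small_phantom_spec(noise_level = 0.05, seed = 13))
  est1 <- segment_layers(ph$scan)
  inv <- ph$scan
  inv$image <- max(inv$image) + min(inv$image) - inv$image
  pol <- seg_config()$polarity
  flipped <- ifelse(pol == "dark_to_light", "light_to_dark", "dark_to_light")
  names(flipped) <- names(pol)
  est2 <- segment_layers(inv, seg_config(polarity = flipped))
  expect_true(all(abs(as.matrix(est1) - as.matrix(est2)) <= 0.5))
})

test_that("boundary_error converts pixel offsets to microns correctly", {
  ph <- generate_bscan(small_phantom_spec(noise_level = 0, seed = 2))
  same <- boundary_error(ph$truth, ph$truth)
  expect_equal(same$mae_um, rep(0, 9))
  expect_equal(same$max_um, rep(0, 9))

  shifted <- boundary_set(as.matrix(ph$truth) + 2, ph$truth$meta)
  be <- boundary_error(ph$truth, shifted, axial_scale = 3.87)
  expect_equal(be$mae_um, rep(7.74, 9))
  expect_equal(be$rmse_um, rep(7.74, 9))

  set.seed(30)
  rows_jit <- as.matrix(ph$truth) + matrix(rnorm(9 * 360, 0, 0.2), 9)
  rows_jit <- apply(rows_jit, 2, sort) # keep anatomical ordering
  jitter <- boundary_set(rows_jit, ph$truth$meta)
  be <- boundary_error(ph$truth, jitter)
  expect_true(all(be$mae_um <= be$rmse_um + 1e-12))
  expect_true(all(be$rmse_um <= be$max_um + 1e-12))
})

test_that("width mismatches are rejected", {
  ph1 <- generate_bscan(small_phantom_spec(noise_level = 0, seed = 2))
  ph2 <- generate_bscan(phantom_spec(image_width = 400, noise_level = 0,
                                     seed = 2))
  expect_error(boundary_error(ph1$truth, ph2$truth), "mismatched widths")
})

test_that("pre-flattening leaves a flat phantom's segmentation intact", {
  ph <- generate_bscan(small_phantom_spec(noise_level = 0.05, seed = 21))
  e1 <- segment_layers(ph$scan)
  e2 <- segment_layers(ph$scan, seg_config(flatten = TRUE))
  expect_lt(mean(abs(as.matrix(e1) - as.matrix(e2))), 0.6)
})
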