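test_that("degenerate flat phantom reproduces its base rows exactly", {
  rows <- c(150, 155, 165, 170, 173, 189, 193, 199, 206)
  spec <- phantom_spec(noise_level = 0, blur_sigma = 0, pit_depth = 0,
                       base_boundary_rows = rows)
  ph <- generate_bscan(spec)
  b <- as.matrix(ph$truth)
  for (k in 1:9) expect_equal(unname(b[k, ]), rep(rows[k], 512))
  ## piecewise-constant image away from boundaries
  expect_equal(unname(ph$scan$image[50, 10]), 10)
  expect_equal(unname(ph$scan$image[400, 10]), 70)
})

test_that("a centered pit gives a mirror-symmetric total-thickness truth", {
  spec <- phantom_spec(noise_level = 0, pit_center_column = 256)
  ph <- generate_bscan(spec)
  tot <- boundaries_to_thickness(ph$truth)$total
  d <- 1:200
  expect_equal(tot[256 - d], tot[256 + d], tolerance = 1e-12)
})

test_that("identical spec + seed is bit-identical; different seeds differ", {
  s1 <- generate_bscan(phantom_spec(noise_level = 0.2, seed = 11))
  s2 <- generate_bscan(phantom_spec(noise_level = 0.2, seed = 11))
  s3 <- generate_bscan(phantom_spec(noise_level = 0.2, seed = 12))
  expect_identical(s1$scan$image, s2$scan$image)
  expect_identical(as.matrix(s1$truth), as.matrix(s2$truth))
  expect_false(identical(s1$scan$image, s3$scan$image))
})

test_that("default boundary spacing reproduces the reference control nasal thicknesses", {
  spec <- phantom_spec(noise_level = 0)
  ph <- generate_bscan(spec)
  th <- boundaries_to_thickness(ph$truth)
  ref <- foveal_thickness_reference()
  ref <- ref[ref$region == "nasal" & ref$group == "control" &
               ref$layer != "total", ]
  for (l in layer_names()) {
    expect_lt(abs(th$layers[l, 1] - ref$mean[ref$layer == l]),
              spec$axial_scale / 2)
  }
})

test_that("ground-truth boundaries are ordered and pinch at the pit center", {
  ph <- generate_bscan(phantom_spec(noise_level = 0.1, seed = 3))
  b <- as.matrix(ph$truth)
  expect_true(all(diff(b[, sample(512, 50)]) >= -1e-9))
  th <- boundaries_to_thickness(ph$truth)
  inner <- colSums(th$layers[c("nfl", "gcl_ipl", "inl", "opl"), ])
  expect_equal(inner[256], 0, tolerance = 1e-9)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(base_boundary_rows = c(9:1) * 20),
               "strictly increasing")
  expect_error(phantom_spec(pit_depth = 5000), "ordering|outside")
  expect_error(phantom_spec(noise_level = 1.2), "noise_level")
  expect_error(phantom_spec(layer_intensities = rep(100, 10)),
               "min_contrast")
})
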