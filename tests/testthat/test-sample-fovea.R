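## one asymmetric eye: nasal/temporal (horizontal) and superior/inferior
## (vertical) layer stacks differ between the two image sides
asym_phantom <- function(meridian, noise = 0, seed = 1) {
  left <- default_rows <- phantom_spec()$base_boundary_rows
  right <- left + c(0, cumsum(rep(0.6, 8))) # each layer 0.6 px thicker
  generate_bscan(phantom_spec(meridian = meridian,
                              base_boundary_rows = left,
                              base_boundary_rows_right = right,
                              noise_level = noise, seed = seed))
}

truth_profiles <- function() {
  h <- asym_phantom("horizontal")
  v <- asym_phantom("vertical")
  list(h = boundaries_to_thickness(h$truth),
       v = boundaries_to_thickness(v$truth),
       h_truth = h$truth, v_truth = v$truth)
}

test_that("identical meridian profiles give central values equal to either one", {
  p <- truth_profiles()
  fs <- sample_fovea(p$h, p$v, inner_absence_threshold = 5)
  ch <- find_foveal_center(p$h, inner_absence_threshold = 5)
  expect_equal(fs$central[["total"]], unname(p$h$total[ch]))
  expect_equal(fs$central[["mez"]], unname(p$h$layers["mez", ch]))
})

test_that("peripheral samples match the configured thicknesses at 0.5 mm", {
  p <- truth_profiles()
  fs <- sample_fovea(p$h, p$v, inner_absence_threshold = 5)
  ref <- foveal_thickness_reference()
  ref <- ref[ref$group == "control" & ref$region == "nasal", ]
  for (l in c("mez", "os", "iz_rpe", "hfl_onl")) {
    ## OD: nasal on the low-column side = the left (reference) stack
    expect_lt(abs(fs$peripheral["nasal", l] - ref$mean[ref$layer == l]), 3.87)
    ## temporal side is 0.6 px (2.32 um) thicker per layer
    expect_lt(abs(fs$peripheral["temporal", l] -
                    (ref$mean[ref$layer == l] + 0.6 * 3.87)), 3.87)
  }
  expect_gt(fs$peripheral["temporal", "total"],
            fs$peripheral["nasal", "total"])
})

test_that("mirroring the image columns with a toggled nasal side is equivariant", {
  p <- truth_profiles()
  mirror <- function(prof) {
    W <- ncol(prof$layers)
    prof$layers <- prof$layers[, W:1]
    prof$total <- rev(prof$total)
    prof$nasal_side <- if (identical(prof$nasal_side, "low")) "high" else "low"
    prof
  }
  f1 <- sample_fovea(p$h, p$v, inner_absence_threshold = 5)
  f2 <- sample_fovea(mirror(p$h), p$v, inner_absence_threshold = 5)
  expect_equal(f1$peripheral["nasal", ], f2$peripheral["nasal", ],
               tolerance = 1e-9)
  expect_equal(f1$peripheral["temporal", ], f2$peripheral["temporal", ],
               tolerance = 1e-9)
  expect_equal(f1$central, f2$central, tolerance = 1e-9)
})

test_that("an eccentricity beyond the scan names the offending quadrant", {
  p <- truth_profiles()
  err <- expect_error(sample_fovea(p$h, p$v, eccentricity = 2000,
                                   inner_absence_threshold = 5),
                      "beyond image extent")
  expect_match(conditionMessage(err), "nasal|temporal")
  expect_error(sample_fovea(p$h, p$h, inner_absence_threshold = 5),
               "one horizontal and one vertical")
})

test_that("foveal samples flatten to the long-format row schema", {
  p <- truth_profiles()
  fs <- sample_fovea(p$h, p$v, inner_absence_threshold = 5)
  df <- as.data.frame(fs, subject = "S1", group = "control")
  expect_equal(nrow(df), 5L + 4L * 9L)
  expect_setequal(unique(df$region),
                  c("central", "nasal", "temporal", "superior", "inferior"))
  expect_true(all(df$thickness_um >= 0))
})
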