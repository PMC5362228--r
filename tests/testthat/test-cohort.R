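test_that("n_per_group = 0 yields an empty table with the full schema", {
  coh <- generate_cohort(cohort_spec(n_per_group = 0, seed = 1))
  expect_equal(nrow(coh), 0L)
  expect_true(all(c("subject", "group", "age", "sex", "se_d",
                    "axial_length_mm", "va_logmar", "central_total",
                    "nasal_nfl", "inferior_inl") %in% names(coh)))
  expect_equal(length(setdiff(names(coh), c("subject", "group", "age", "sex",
                                            "se_d", "axial_length_mm",
                                            "va_logmar"))), 41L)
})

test_that("zero SDs reproduce the configured means exactly", {
  tp <- foveal_thickness_reference(); tp$sd <- 0
  bp <- cohort_baseline_reference(); bp$sd <- 0
  coh <- generate_cohort(cohort_spec(n_per_group = 3, thickness_params = tp,
                                     baseline_params = bp,
                                     age_sd = c(amblyopic = 0, control = 0),
                                     seed = 2))
  amb <- coh[coh$group == "amblyopic", ]
  expect_equal(amb$central_total, rep(133.58, 3))
  expect_equal(amb$nasal_nfl, rep(18.26, 3))
  expect_equal(amb$axial_length_mm, rep(21.77, 3))
  expect_equal(amb$age, rep(7.8, 3))
  ctl <- coh[coh$group == "control", ]
  expect_equal(ctl$inferior_inl, rep(22.40, 3))
  expect_equal(ctl$age, rep(7.7, 3))
})

test_that("sample moments recover the configured distribution (law of large numbers)", {
  coh <- generate_cohort(cohort_spec(n_per_group = 2000, seed = 3))
  expect_lt(abs(mean(coh$central_total[coh$group == "fellow"]) - 132.85),
            3 * 9.48 / sqrt(2000))
  expect_lt(abs(sd(coh$nasal_nfl[coh$group == "control"]) - 2.31), 0.2)
})

test_that("paired amblyopic/fellow eyes share identity and correlate as configured", {
  coh <- generate_cohort(cohort_spec(n_per_group = 5000,
                                     paired_eye_correlation = 0.9, seed = 4))
  amb <- coh[coh$group == "amblyopic", ]
  fel <- coh[coh$group == "fellow", ]
  expect_identical(amb$subject, fel$subject)
  expect_identical(amb$age, fel$age)
  expect_identical(amb$sex, fel$sex)
  za <- (amb$nasal_total - 224.95) / 9.92
  zf <- (fel$nasal_total - 217.78) / 11.43
  expect_lt(abs(cor(za, zf) - 0.9), 0.02)
})

test_that("thickness draws are truncated at 0.1 um and ages at the study band", {
  tp <- foveal_thickness_reference()
  tp$mean <- 1; tp$sd <- 5
  coh <- generate_cohort(cohort_spec(n_per_group = 200,
                                     thickness_params = tp, seed = 5))
  th <- as.matrix(coh[, setdiff(names(coh), c("subject", "group", "age",
                                              "sex", "se_d",
                                              "axial_length_mm",
                                              "va_logmar"))])
  expect_gte(min(th), 0.1)
  expect_true(any(th == 0.1)) # the floor is actually hit at these settings
  expect_true(all(coh$age >= 5 & coh$age <= 12))
})

test_that("cohort generation is reproducible and validates its spec", {
  c1 <- generate_cohort(cohort_spec(n_per_group = 10, seed = 9))
  c2 <- generate_cohort(cohort_spec(n_per_group = 10, seed = 9))
  expect_identical(c1, c2)
  expect_error(cohort_spec(paired_eye_correlation = 1.2), "\\[-1, 1\\]")
  tp <- foveal_thickness_reference()
  expect_error(cohort_spec(thickness_params = tp[tp$group != "control", ]),
               "missing group parameters")
})

test_that("cohort_long pivots wide tables losslessly", {
  coh <- generate_cohort(cohort_spec(n_per_group = 4, seed = 6))
  long <- cohort_long(coh)
  expect_equal(nrow(long), nrow(coh) * 41L)
  sel <- long$region == "nasal" & long$layer == "nfl" &
    long$group == "amblyopic"
  expect_equal(long$thickness_um[sel],
               coh$nasal_nfl[coh$group == "amblyopic"])
})
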