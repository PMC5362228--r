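test_that("clinical unit conversions follow their closed forms", {
  expect_equal(spherical_equivalent(4.00, 1.00), 4.50)
  expect_equal(spherical_equivalent(0, 0), 0)
  expect_equal(spherical_equivalent(-1.00, -0.50), -1.25)
  expect_equal(snellen_to_logmar(20, 20), 0)
  expect_equal(snellen_to_logmar(20, 200), 1)
  expect_equal(snellen_to_logmar(20, 40), log10(2))
  expect_error(snellen_to_logmar(0, 20), "positive")
})

test_that("Bonferroni adjustment multiplies, caps, displays and never decreases", {
  a <- bonferroni_adjust(c(0.01, 0.5, 0.4), m = 3)
  expect_equal(a$adjusted, c(0.03, 1, 1))
  expect_equal(a$display, c("0.030", ">0.999", ">0.999"))
  expect_equal(bonferroni_adjust(0.2, m = 1)$adjusted, 0.2)
  p <- runif(50)
  adj <- bonferroni_adjust(p, 3)$adjusted
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_identical(order(adj[order(p)]), seq_len(50)) # order-preserving
  expect_error(bonferroni_adjust(1.4), "\\[0, 1\\]")
  ## display threshold: > 0.999 shown only above 0.9995
  expect_equal(bonferroni_adjust(c(0.333, 0.3332), 3)$display,
               c("0.999", ">0.999"))
})

test_that("ANCOVA matches an explicit normal-equations solution on a fixed table", {
  toy <- data.frame(
    subject = sprintf("S%02d", 1:12),
    group = rep(c("amblyopic", "fellow", "control"), each = 4),
    age = c(6, 8, 9, 11, 7, 6, 10, 8, 9, 7, 6, 10),
    sex = c("M", "F", "M", "M", "F", "M", "F", "M", "M", "F", "M", "F"),
    y = c(18.1, 17.4, 19.0, 18.6, 16.2, 17.0, 16.8, 15.9,
          16.5, 15.8, 16.1, 17.2))
  toy$nasal_nfl <- toy$y
  fit <- ancova_group_compare(toy, "nasal_nfl")
  orc <- ancova_oracle(toy$y, toy$group, toy$age,
                       as.numeric(toy$sex == "M"))
  expect_equal(unname(coef(fit)), orc$beta, tolerance = 1e-6)
  expect_equal(fit$f_group, orc$F, tolerance = 1e-6)
  expect_equal(fit$df_group, orc$df)
  ## adjusted p never below raw p, capped at 1
  expect_true(all(fit$pairwise$p_adjusted >= fit$pairwise$p_raw))
  expect_true(all(fit$pairwise$p_adjusted <= 1))
})

test_that("with balanced, irrelevant covariates the ANCOVA reduces to one-way ANOVA", {
  ## covariate pattern identical in every group; residual pattern orthogonal
  ## to [1, age, sex] so the covariate coefficients are exactly zero
  age <- c(6, 7, 8, 9, 10, 11)
  sexM <- c(1, 1, 1, 0, 0, 0)
  e <- qr.resid(qr(cbind(1, age, sexM)), c(1.2, -0.7, 0.4, 0.9, -1.1, -0.7))
  df <- data.frame(group = rep(c("amblyopic", "fellow", "control"), each = 6),
                   age = rep(age, 3),
                   sex = rep(ifelse(sexM == 1, "M", "F"), 3),
                   nasal_nfl = rep(c(18, 16.5, 16), each = 6) + rep(e, 3))
  fit <- ancova_group_compare(df, "nasal_nfl")
  expect_equal(unname(coef(fit)[c("age_c", "sexM")]), c(0, 0),
               tolerance = 1e-9)
  expect_equal(unname(fit$adjusted_means), unname(fit$group_means),
               tolerance = 1e-6)
  aov_fit <- anova(lm(nasal_nfl ~ group, data = df))
  ancova_rss <- sum(residuals(fit$fit)^2)
  expect_equal(ancova_rss, aov_fit["Residuals", "Sum Sq"], tolerance = 1e-9)
  ## F statistics agree once the error degrees of freedom are matched
  expect_equal(fit$f_group * (ancova_rss / fit$df_group[2]),
               aov_fit["group", "F value"] *
                 (aov_fit["Residuals", "Sum Sq"] / aov_fit["Residuals", "Df"]),
               tolerance = 1e-9)
})

test_that("rank-deficient ANCOVA designs raise an explicit error", {
  df <- data.frame(group = rep(c("amblyopic", "fellow", "control"), each = 4),
                   age = rep(c(6, 7, 8, 9), 3),
                   sex = "M", # single-sex cohort: sex collinear
                   nasal_nfl = rnorm(12, 17))
  expect_error(ancova_group_compare(df, "nasal_nfl"), "rank-deficient")
  expect_error(ancova_group_compare(df[1:5, ], "nasal_nfl"), "at least 2")
})

test_that("Welch t matches its closed form and detects the axial length difference", {
  coh <- data.frame(group = rep(c("amblyopic", "fellow"), each = 6),
                    axial_length_mm = c(21.3, 21.9, 22.1, 21.5, 21.8, 22.4,
                                        23.0, 23.4, 22.9, 23.6, 23.1, 23.3))
  bc <- baseline_compare(coh, "axial_length_mm", "amblyopic", "fellow")
  orc <- welch_oracle(coh$axial_length_mm[1:6], coh$axial_length_mm[7:12])
  expect_equal(bc$t, orc$t, tolerance = 1e-9)
  expect_equal(bc$df, orc$df, tolerance = 1e-9)
  expect_equal(bc$p, orc$p, tolerance = 1e-9)

  ## identical groups: t = 0, p = 1
  same <- data.frame(group = rep(c("amblyopic", "fellow"), each = 4),
                     axial_length_mm = rep(c(21, 22, 23, 24), 2))
  bc0 <- baseline_compare(same, "axial_length_mm", "amblyopic", "fellow")
  expect_equal(bc0$t, 0)
  expect_equal(bc0$p, 1)
  expect_error(baseline_compare(same, "axial_length_mm", "amblyopic", "x"),
               "at least 2")
})

test_that("axial length separates amblyopic from fellow eyes with near-certain significance", {
  ## power oracle: exact noncentral-t power at the configured parameters,
  ## with a 3-sigma binomial band for the observed replicate fraction
  n <- 18; m1 <- 21.77; s1 <- 0.68; m2 <- 23.17; s2 <- 0.75
  se <- sqrt(s1^2 / n + s2^2 / n)
  df <- se^4 / ((s1^2 / n)^2 / (n - 1) + (s2^2 / n)^2 / (n - 1))
  crit <- qt(1 - 0.001 / 2, df)
  ncp <- (m2 - m1) / se
  power <- suppressWarnings(pt(-crit, df, -ncp) + 1 - pt(crit, df, -ncp))
  reps <- 300
  set.seed(314)
  res <- replicate(reps, {
    bc <- baseline_compare(
      data.frame(group = rep(c("amblyopic", "fellow"), each = n),
                 axial_length_mm = c(rnorm(n, m1, s1), rnorm(n, m2, s2))),
      "axial_length_mm", "amblyopic", "fellow")
    c(hit = bc$p < 0.001, t = bc$t)
  })
  expect_gte(mean(res["hit", ]),
             power - 3 * sqrt(power * (1 - power) / reps))
  expect_true(all(res["t", ] < 0)) # amblyopic eyes shorter
})

test_that("Pearson correlation matches its covariance formula and null distribution", {
  x <- c(21.1, 22.4, 21.9, 23.0, 22.2, 21.5, 22.8, 23.3, 21.7, 22.0)
  y <- c(17.9, 16.2, 16.8, 15.1, 16.5, 17.5, 15.8, 15.2, 17.2, 16.9)
  coh <- data.frame(subject = sprintf("S%d", 1:10), group = "amblyopic",
                    axial_length_mm = x, nasal_nfl = y)
  cr <- correlate_thickness(coh, "axial_length_mm", "nasal_nfl")
  orc <- pearson_oracle(x, y)
  expect_equal(cr$r, orc$r, tolerance = 1e-9)
  expect_equal(cr$p, orc$p, tolerance = 1e-9)
  expect_equal(cr$n, 10L)

  ## exact linear relation
  coh$nasal_nfl <- 2 * x + 1
  expect_equal(correlate_thickness(coh, "axial_length_mm", "nasal_nfl")$r, 1)

  ## null distribution of r at n = 54: |r| < 0.27 with the exact t-transform
  ## probability, minus a 3-sigma binomial allowance
  n <- 54; reps <- 200
  q <- 0.27 * sqrt(n - 2) / sqrt(1 - 0.27^2)
  p0 <- 2 * pt(q, n - 2) - 1
  set.seed(2718)
  frac <- mean(replicate(reps, {
    coh <- data.frame(subject = seq_len(n), group = "amblyopic",
                      axial_length_mm = rnorm(n), nasal_nfl = rnorm(n))
    abs(correlate_thickness(coh, "axial_length_mm", "nasal_nfl")$r) < 0.27
  }))
  expect_gte(frac, p0 - 3 * sqrt(p0 * (1 - p0) / reps))

  coh$nasal_nfl <- 5
  expect_error(correlate_thickness(coh, "axial_length_mm", "nasal_nfl"),
               "zero variance")
})

test_that("interocular acuity difference is computed per subject", {
  coh <- generate_cohort(cohort_spec(n_per_group = 18, seed = 8))
  cr <- correlate_thickness(coh, "va_interocular_difference", "central_os")
  expect_equal(cr$n, 18L)
  expect_true(abs(cr$r) <= 1)
})

test_that("group mean differences reproduce the reference worked examples and antisymmetry", {
  ref <- foveal_thickness_reference()
  expect_equal(group_mean_difference(ref, c("nasal", "nfl"),
                                     "amblyopic", "control"), 1.88)
  expect_equal(group_mean_difference(ref, c("inferior", "inl"),
                                     "amblyopic", "control"), 3.14)
  expect_equal(group_mean_difference(ref, "nasal_nfl", "fellow", "fellow"), 0)
  expect_equal(group_mean_difference(ref, "nasal_nfl", "control", "amblyopic"),
               -group_mean_difference(ref, "nasal_nfl", "amblyopic",
                                      "control"))
  expect_error(group_mean_difference(ref, c("nasal", "bogus"),
                                     "amblyopic", "control"), "not present")
})

test_that("layer_report assembles a table-shaped summary over outcomes", {
  coh <- generate_cohort(cohort_spec(n_per_group = 18, seed = 10))
  rep <- layer_report(coh, c("nasal_nfl", "inferior_inl", "central_total"))
  expect_equal(nrow(rep), 3L)
  expect_true(all(c("amblyopic_mean", "control_sd", "p_group",
                    "display_fellow_vs_control") %in% names(rep)))
  ## report feeds group_mean_difference too
  d <- group_mean_difference(rep, "nasal_nfl", "amblyopic", "control")
  expect_equal(d, mean(coh$nasal_nfl[coh$group == "amblyopic"]) -
                 mean(coh$nasal_nfl[coh$group == "control"]))
  expect_true(all(rep$p_amblyopic_vs_fellow >= 0 &
                    rep$p_amblyopic_vs_fellow <= 1))
})
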