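## Group-comparison statistics ------------------------------------------------

#' Spherical equivalent refraction
#'
#' `SE = sphere + cylinder / 2`, in diopters.
#'
#' @param sphere,cylinder Dioptric powers.
#' @return Spherical equivalent, diopters.
#' @export
spherical_equivalent <- function(sphere, cylinder) {
  stopifnot(is.finite(sphere), is.finite(cylinder))
  sphere + cylinder / 2
}

#' Snellen fraction to logMAR
#'
#' `logMAR = log10(denominator / numerator)`; 20/20 maps to 0.
#'
#' @param numerator,denominator Snellen fraction components (positive).
#' @return Visual acuity in logMAR.
#' @export
snellen_to_logmar <- function(numerator, denominator) {
  if (any(numerator <= 0) || any(denominator <= 0))
    stop("Snellen numerator and denominator must be positive")
  log10(denominator / numerator)
}

#' Bonferroni adjustment with display convention
#'
#' Multiplies each p-value by the family size `m` and caps at 1. Display
#' strings use three decimals, with values above 0.9995 shown as
#' `">0.999"`.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Family size (default 3, the three pairwise group contrasts).
#' @return List with `adjusted` and `display`.
#' @export
bonferroni_adjust <- function(p, m = 3L) {
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (m < 1L) stop("family size m must be >= 1")
  adjusted <- pmin(1, m * p)
  list(adjusted = adjusted, display = format_p(adjusted))
}

format_p <- function(p) ifelse(p > 0.9995, ">0.999", sprintf("%.3f", p))

resolve_outcome <- function(cohort, outcome) {
  if (length(outcome) == 2L) outcome <- paste(outcome, collapse = "_")
  if (!outcome %in% names(cohort))
    stop("outcome '", outcome, "' not found in the cohort table")
  outcome
}

#' Three-group ANCOVA with Bonferroni pairwise contrasts
#'
#' Fits `thickness ~ group + age + sex` by least squares (age centered, sex
#' as a male indicator), reports the group-term F-test, and compares the
#' covariate-adjusted group means pairwise with model-based t-tests whose
#' p-values are Bonferroni-multiplied by 3 and capped at 1.
#'
#' @param cohort An `oct_cohort` (or compatible data frame with columns
#'   `group`, `age`, `sex` and the outcome).
#' @param outcome Thickness column name (e.g. `"nasal_nfl"`) or a
#'   `c(region, layer)` pair.
#' @return An object of class `layer_ancova`: group F statistic, df and
#'   p-value; raw and adjusted group means/SDs; raw, Bonferroni-adjusted
#'   and display p-values for the three pairwise contrasts.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 18, seed = 1))
#' ancova_group_compare(coh, c("nasal", "nfl"))
ancova_group_compare <- function(cohort, outcome) {
  outcome <- resolve_outcome(cohort, outcome)
  df <- data.frame(y = cohort[[outcome]],
                   group = factor(cohort$group, levels = .GROUPS),
                   age = cohort$age,
                   sexM = as.numeric(cohort$sex == "M"))
  df <- df[complete.cases(df), ]
  counts <- table(df$group)
  if (any(counts < 2L))
    stop("each group needs at least 2 subjects (got ",
         paste(counts, collapse = "/"), ")")
  df$age_c <- df$age - mean(df$age)

  fit <- lm(y ~ group + age_c + sexM, data = df)
  if (any(is.na(coef(fit))))
    stop("rank-deficient ANCOVA design (collinear covariates, ",
         "e.g. a single-sex group)")
  fit0 <- lm(y ~ age_c + sexM, data = df)
  a <- anova(fit0, fit)

  b <- coef(fit)
  V <- vcov(fit)
  sex_bar <- mean(df$sexM)
  ## adjusted means: prediction at age_c = 0, sexM = sample mean
  Lg <- rbind(amblyopic = c(1, 0, 0, 0, sex_bar),
              fellow    = c(1, 1, 0, 0, sex_bar),
              control   = c(1, 0, 1, 0, sex_bar))
  adj_means <- as.numeric(Lg %*% b)
  names(adj_means) <- .GROUPS

  pairs <- list(amblyopic_vs_fellow = c("amblyopic", "fellow"),
                amblyopic_vs_control = c("amblyopic", "control"),
                fellow_vs_control = c("fellow", "control"))
  df_res <- fit$df.residual
  p_raw <- t_stat <- diff_adj <- setNames(numeric(3), names(pairs))
  for (nm in names(pairs)) {
    L <- Lg[pairs[[nm]][1], ] - Lg[pairs[[nm]][2], ]
    est <- sum(L * b)
    se <- sqrt(as.numeric(t(L) %*% V %*% L))
    t_stat[nm] <- est / se
    diff_adj[nm] <- est
    p_raw[nm] <- 2 * pt(-abs(t_stat[nm]), df_res)
  }
  adj <- bonferroni_adjust(p_raw, 3L)

  raw_mean <- c(tapply(df$y, df$group, mean))
  raw_sd <- c(tapply(df$y, df$group, sd))

  structure(list(
    outcome = outcome,
    n = as.integer(counts),
    f_group = a$F[2], df_group = c(a$Df[2], df_res),
    p_group = a$`Pr(>F)`[2],
    group_means = raw_mean[.GROUPS], group_sds = raw_sd[.GROUPS],
    adjusted_means = adj_means,
    pairwise = data.frame(
      contrast = names(pairs),
      difference = diff_adj, t = t_stat, p_raw = p_raw,
      p_adjusted = adj$adjusted, display = adj$display,
      row.names = NULL, stringsAsFactors = FALSE),
    fit = fit
  ), class = "layer_ancova")
}

#' @export
print.layer_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA (thickness ~ group + age + sex): %s\n", x$outcome))
  cat(sprintf("  group F(%d, %d) = %.3f, p = %s\n",
              x$df_group[1], x$df_group[2], x$f_group,
              format_p(x$p_group)))
  for (g in .GROUPS) {
    cat(sprintf("  %-10s %6.2f +/- %5.2f um (adjusted %6.2f), n = %d\n",
                g, x$group_means[[g]], x$group_sds[[g]],
                x$adjusted_means[[g]], x$n[match(g, .GROUPS)]))
  }
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %-22s diff %6.2f um, Bonferroni p = %s\n",
                pw$contrast[i], pw$difference[i], pw$display[i]))
  }
  invisible(x)
}

#' @export
summary.layer_ancova <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.layer_ancova <- function(object, ...) coef(object$fit)

#' Baseline two-group comparison (Welch t-test)
#'
#' @param cohort Cohort table with columns `group` and the variable.
#' @param variable One of `"se_d"`, `"axial_length_mm"`, `"va_logmar"` (or
#'   any numeric column).
#' @param g1,g2 Group labels to compare.
#' @param welch Use the unequal-variance Welch test (default); `FALSE`
#'   pools variances.
#' @return List with `t`, `df`, `p`, `means` and the group labels.
#' @export
baseline_compare <- function(cohort, variable, g1, g2, welch = TRUE) {
  if (!variable %in% names(cohort)) stop("variable '", variable, "' not found")
  x <- cohort[[variable]][cohort$group == g1]
  y <- cohort[[variable]][cohort$group == g2]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  tt <- t.test(x, y, var.equal = !welch)
  list(variable = variable, groups = c(g1, g2),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, means = setNames(c(mean(x), mean(y)), c(g1, g2)))
}

#' Pearson correlation between a clinical variable and a thickness
#'
#' Pearson r with the two-sided p-value from the t transform with `n - 2`
#' degrees of freedom. By default computed on amblyopic eyes;
#' `x = "va_interocular_difference"` uses each subject's amblyopic-minus-
#' fellow logMAR difference (the severity of amblyopia).
#'
#' @param cohort An `oct_cohort`.
#' @param x `"axial_length_mm"`, `"se_d"`, `"va_logmar"` or
#'   `"va_interocular_difference"`.
#' @param outcome Thickness column name or `c(region, layer)`.
#' @param group Group whose eyes enter the correlation (default
#'   `"amblyopic"`).
#' @return An object of class `correlation_result`: `r`, `p`, `n` and the
#'   variable pair.
#' @export
correlate_thickness <- function(cohort, x, outcome, group = "amblyopic") {
  outcome <- resolve_outcome(cohort, outcome)
  rows <- cohort[cohort$group == group, ]
  if (identical(x, "va_interocular_difference")) {
    amb <- cohort[cohort$group == "amblyopic", ]
    fel <- cohort[cohort$group == "fellow", ]
    d <- amb$va_logmar - fel$va_logmar[match(amb$subject, fel$subject)]
    xv <- d[match(rows$subject, amb$subject)]
  } else {
    if (!x %in% names(cohort)) stop("variable '", x, "' not found")
    xv <- rows[[x]]
  }
  yv <- rows[[outcome]]
  ok <- complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0)
    stop("zero variance in '", x, "' or '", outcome, "'")
  ct <- cor.test(xv, yv, method = "pearson")
  structure(list(x = x, outcome = outcome, group = group,
                 r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r(%s, %s | %s eyes) = %.3f, p = %s, n = %d\n",
              x$x, x$outcome, x$group, x$r, format_p(x$p), x$n))
  invisible(x)
}

#' Table-style group-comparison report over many outcomes
#'
#' Runs [ancova_group_compare()] on every requested thickness outcome and
#' assembles a report with per-group means +/- SD and the three
#' Bonferroni-adjusted pairwise p-values (with display strings).
#'
#' @param cohort An `oct_cohort`.
#' @param outcomes Character vector of thickness columns; default all.
#' @return A data frame of class `layer_report`.
#' @export
layer_report <- function(cohort, outcomes = NULL) {
  outcomes <- outcomes %||% thickness_columns(cohort)
  rl <- split_measurement(outcomes)
  rows <- lapply(seq_along(outcomes), function(i) {
    a <- ancova_group_compare(cohort, outcomes[i])
    data.frame(
      region = rl$region[i], layer = rl$layer[i],
      amblyopic_mean = a$group_means[["amblyopic"]],
      amblyopic_sd = a$group_sds[["amblyopic"]],
      fellow_mean = a$group_means[["fellow"]],
      fellow_sd = a$group_sds[["fellow"]],
      control_mean = a$group_means[["control"]],
      control_sd = a$group_sds[["control"]],
      f_group = a$f_group, p_group = a$p_group,
      p_amblyopic_vs_fellow = a$pairwise$p_adjusted[1],
      p_amblyopic_vs_control = a$pairwise$p_adjusted[2],
      p_fellow_vs_control = a$pairwise$p_adjusted[3],
      display_amblyopic_vs_fellow = a$pairwise$display[1],
      display_amblyopic_vs_control = a$pairwise$display[2],
      display_fellow_vs_control = a$pairwise$display[3],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("layer_report", "data.frame")
  out
}

#' Difference of group means for one outcome
#'
#' `mean(g1) - mean(g2)` looked up from a means table: either a
#' [layer_report()] (columns `<group>_mean`) or a parameter table in the
#' shape of [foveal_thickness_reference()] (columns `group`, `mean`).
#'
#' @param means A `layer_report` or reference-parameter data frame.
#' @param outcome `c(region, layer)` or a `region_layer` string.
#' @param g1,g2 Group labels.
#' @return Difference in micrometers.
#' @export
#' @examples
#' group_mean_difference(foveal_thickness_reference(),
#'                       c("nasal", "nfl"), "amblyopic", "control")
group_mean_difference <- function(means, outcome, g1, g2) {
  if (length(outcome) == 1L) {
    rl <- split_measurement(outcome)
    outcome <- c(rl$region, rl$layer)
  }
  sel <- means$region == outcome[1] & means$layer == outcome[2]
  if (!any(sel)) stop("outcome ", paste(outcome, collapse = "/"),
                      " not present in the means table")
  get_mean <- function(g) {
    col <- paste0(g, "_mean")
    if (col %in% names(means)) return(means[[col]][which(sel)[1]])
    v <- means$mean[sel & means$group == g]
    if (length(v) != 1L) stop("missing cell: group '", g, "' for outcome ",
                              paste(outcome, collapse = "/"))
    v
  }
  get_mean(g1) - get_mean(g2)
}
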