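#' Assign the study age groups
#'
#' Group 1: age <= 25, Group 2: 26--35, Group 3: 36--45, Group 4: >= 46.
#' Fractional ages are floored before grouping.
#'
#' @param age_years numeric ages.
#' @return Factor with levels `G1..G4`.
#' @export
age_group <- function(age_years) {
  a <- floor(age_years)
  cut(a, breaks = c(-Inf, 25, 35, 45, Inf), labels = paste0("G", 1:4))
}

metric_region_cols <- function(table, metrics, regions) {
  cols <- expand.grid(metric = metrics, region = regions,
                      stringsAsFactors = FALSE)
  cols$column <- paste(cols$metric, cols$region, sep = "_")
  missing <- setdiff(cols$column, names(table))
  if (length(missing))
    stop_validation("missing metric columns: ", paste(missing, collapse = ", "))
  cols
}

#' Sex-difference GEE analysis per metric and region
#'
#' For each `<metric>_<region>` column, fits an exchangeable GEE with sex as
#' the sole covariate (cluster = subject) and reports the male - female
#' coefficient with robust 95% CI and Wald p, alongside the per-sex raw
#' means and SDs.
#'
#' @param table eye-level cohort data frame with `subject_id`, `sex`
#'   (`M`/`F`), and metric columns.
#' @param metrics,regions character vectors naming the columns to analyse
#'   (as `<metric>_<region>`).
#' @return Data frame, one row per metric x region: group means +- SD,
#'   `beta` (male - female), `se`, `ci_lower`, `ci_upper`, `p`.
#' @export
sex_difference_analysis <- function(table,
                                    metrics = c("Df", "VAR", "Dm", "tau"),
                                    regions = c("whole", "inner_ring", "outer_ring")) {
  if (length(unique(table$sex)) < 2)
    stop_validation("both sexes must be present")
  cols <- metric_region_cols(table, metrics, regions)
  table$sex <- factor(table$sex, levels = c("F", "M"))
  out <- lapply(seq_len(nrow(cols)), function(i) {
    cn <- cols$column[i]
    fit <- gee_exch(stats::as.formula(paste(cn, "~ sex")), table, "subject_id")
    s <- summary(fit)$coefficients["sexM", ]
    m <- table[[cn]]
    data.frame(metric = cols$metric[i], region = cols$region[i],
               mean_male = mean(m[table$sex == "M"]),
               sd_male = stats::sd(m[table$sex == "M"]),
               mean_female = mean(m[table$sex == "F"]),
               sd_female = stats::sd(m[table$sex == "F"]),
               beta = s[["Estimate"]], se = s[["Robust SE"]],
               ci_lower = s[["CI lower"]], ci_upper = s[["CI upper"]],
               p = s[["Pr(>|z|)"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Age-association GEE analysis per metric and region
#'
#' Fits an exchangeable GEE with age in years (continuous) as the sole
#' covariate for each metric column.
#'
#' @inheritParams sex_difference_analysis
#' @return Data frame with `beta` (per year), `se`, 95% CI and Wald `p` per
#'   metric x region.
#' @export
age_association_analysis <- function(table,
                                     metrics = c("Df", "VAR", "Dm", "tau"),
                                     regions = c("whole", "inner_ring", "outer_ring")) {
  if (length(unique(table$age_years)) < 2)
    stop_validation("age must vary")
  cols <- metric_region_cols(table, metrics, regions)
  out <- lapply(seq_len(nrow(cols)), function(i) {
    cn <- cols$column[i]
    fit <- gee_exch(stats::as.formula(paste(cn, "~ age_years")), table,
                    "subject_id")
    s <- summary(fit)$coefficients["age_years", ]
    data.frame(metric = cols$metric[i], region = cols$region[i],
               beta = s[["Estimate"]], se = s[["Robust SE"]],
               ci_lower = s[["CI lower"]], ci_upper = s[["CI upper"]],
               p = s[["Pr(>|z|)"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise age-group comparison with sex as covariate
#'
#' Fits one exchangeable GEE per metric with age-group indicators plus sex,
#' and reports all six pairwise group contrasts (G1-G2, G1-G3, G1-G4,
#' G2-G3, G2-G4, G3-G4) with robust Wald p-values. No multiple-testing
#' adjustment is applied by default; set `adjust` to `"bonferroni"` or
#' `"holm"` to adjust within each metric x region.
#'
#' @inheritParams sex_difference_analysis
#' @param adjust p-value adjustment across the six contrasts
#'   (`"none"` default).
#' @return Data frame, one row per metric x region x contrast: `estimate`
#'   (first group minus second), `se`, `p`. Contrasts involving an empty
#'   group are returned with `NA` estimates and `defined = FALSE`.
#' @export
age_group_comparison <- function(table,
                                 metrics = c("Df", "VAR", "Dm", "tau"),
                                 regions = c("whole", "inner_ring", "outer_ring"),
                                 adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  table$age_group <- age_group(table$age_years)
  present <- levels(droplevels(table$age_group))
  if (length(present) < 2) stop_validation("need >= 2 nonempty age groups")
  table$sex <- factor(table$sex, levels = c("F", "M"))
  cols <- metric_region_cols(table, metrics, regions)
  pairs <- utils::combn(paste0("G", 1:4), 2)
  out <- lapply(seq_len(nrow(cols)), function(i) {
    cn <- cols$column[i]
    dat <- droplevels(table)
    fit <- gee_exch(stats::as.formula(paste(cn, "~ age_group + sex")), dat,
                    "subject_id")
    cf <- names(stats::coef(fit))
    res <- lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      if (!(g1 %in% present) || !(g2 %in% present)) {
        return(data.frame(metric = cols$metric[i], region = cols$region[i],
                          contrast = paste0(g1, "-", g2), estimate = NA_real_,
                          se = NA_real_, p = NA_real_, defined = FALSE))
      }
      L <- stats::setNames(numeric(length(cf)), cf)
      k1 <- paste0("age_group", g1); k2 <- paste0("age_group", g2)
      if (k1 %in% cf) L[k1] <- 1   # reference group has no coefficient
      if (k2 %in% cf) L[k2] <- -1
      ct <- gee_contrast(fit, L)
      data.frame(metric = cols$metric[i], region = cols$region[i],
                 contrast = paste0(g1, "-", g2),
                 estimate = ct[["estimate"]], se = ct[["se"]],
                 p = ct[["p"]], defined = TRUE)
    })
    res <- do.call(rbind, res)
    if (adjust != "none")
      res$p <- stats::p.adjust(res$p, method = adjust)
    res
  })
  do.call(rbind, out)
}

#' Two-sample t test from summary statistics
#'
#' The independent-samples t statistic computed directly from group means,
#' SDs and sizes, either with the pooled-variance formula or the
#' unequal-variance (Welch) formula with Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (`n >= 2`, `sd >= 0`).
#' @param variant `"pooled"` or `"welch"`.
#' @return A `macvasc_test` list: `statistic`, `df`, `p`, `method`. With
#'   zero variance in both groups the statistic is 0 for equal means and
#'   `Inf` (flagged) for unequal means.
#' @examples
#' t_test_from_summary(22.896, 1.525, 96, 22.778, 1.278, 108)$statistic
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop_validation("group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop_validation("SDs must be >= 0")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    stat <- if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2)
    return(structure(list(statistic = stat, df = df,
                          p = if (is.finite(stat)) 1 else 0,
                          method = paste0(variant, "-t"),
                          degenerate = !is.finite(stat)),
                     class = "macvasc_test"))
  }
  stat <- (mean1 - mean2) / se
  structure(list(statistic = stat, df = df,
                 p = 2 * stats::pt(-abs(stat), df),
                 method = paste0(variant, "-t"), degenerate = FALSE),
            class = "macvasc_test")
}

#' @export
print.macvasc_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      ", df = ", signif(x$df, 5), ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Chi-square test of the sex ratio across groups
#'
#' Pearson chi-square on a 2 x k table of male/female counts per group,
#' without continuity correction; `df = k - 1`.
#'
#' @param counts 2 x k matrix (rows: the two sexes; columns: groups).
#' @return A `macvasc_test` with `statistic`, `df`, `p`.
#' @export
chi_square_sex_ratio <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop_validation("counts must have 2 rows")
  exp_counts <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(exp_counts <= 0)) stop_validation("all expected counts must be > 0")
  ct <- stats::chisq.test(counts, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, method = "chi-square", degenerate = FALSE),
            class = "macvasc_test")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard routine, with the study's validity
#' window (3 <= n <= 5000) enforced and constant input rejected.
#'
#' @param values numeric sample.
#' @return A `macvasc_test` with `statistic` (W), `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop_validation("need 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop_validation("input is constant")
  sw <- stats::shapiro.test(values)
  structure(list(statistic = unname(sw$statistic), df = NA_real_,
                 p = sw$p.value, method = "shapiro-wilk", degenerate = FALSE),
            class = "macvasc_test")
}

#' Scatterplot of a metric against age with the GEE fit line
#'
#' Eye-level values against age, with the marginal regression line from the
#' exchangeable GEE (age as sole covariate) overlaid.
#'
#' @param table eye-level cohort table.
#' @param metric_col name of the metric column, e.g. `"Df_whole"`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the fitted [gee_exch()] object.
#' @export
plot_age_association <- function(table, metric_col, ...) {
  fit <- gee_exch(stats::as.formula(paste(metric_col, "~ age_years")), table,
                  "subject_id")
  graphics::plot(table$age_years, table[[metric_col]],
                 xlab = "Age (years)", ylab = metric_col,
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(coef(fit)[1], coef(fit)[2], lwd = 2, col = "firebrick")
  invisible(fit)
}

#' Baseline mean +- SD table by sex and age group
#'
#' Stratifies the eye-level table by sex x age group and reports the mean
#' and SD of every `<metric>_<region>` column per stratum, flagging the SD
#' of single-eye strata as undefined.
#'
#' @inheritParams sex_difference_analysis
#' @return Long data frame: `sex, age_group, metric, region, n, mean, sd,
#'   sd_defined` (one row per nonempty stratum x metric x region).
#' @export
baseline_table <- function(table,
                           metrics = c("Df", "VAR", "Dm", "tau"),
                           regions = c("whole", "inner_ring", "outer_ring")) {
  cols <- metric_region_cols(table, metrics, regions)
  table$age_group <- age_group(table$age_years)
  out <- list()
  for (sx in unique(table$sex)) for (g in levels(table$age_group)) {
    sub <- table[table$sex == sx & table$age_group == g, ]
    if (nrow(sub) == 0) next
    for (i in seq_len(nrow(cols))) {
      v <- sub[[cols$column[i]]]
      out[[length(out) + 1]] <- data.frame(
        sex = sx, age_group = g,
        metric = cols$metric[i], region = cols$region[i],
        n = length(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        sd_defined = length(v) > 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
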