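#' Default generative effect structure for the synthetic cohort
#'
#' One row per metric x ETDRS composite region with the linear-predictor
#' pieces used by [generate_cohort()].
#'
#' @details `base` is the expected value for a female eye at the reference
#'   age (33 years, roughly the study population mean), `b_sex` the
#'   male - female shift, `b_age` the change per year of age, and `sd_tot`
#'   the total between-eye SD (subject + eye components combined). The sex
#'   and age effects for Df/VAR/Dm and the SDs reproduce the magnitudes
#'   reported for healthy macular vasculature on fundus photographs;
#'   tortuosity carries no sex or age effect by construction.
#' @return Data frame with columns `metric`, `region`, `base`, `b_sex`,
#'   `b_age`, `sd_tot`.
#' @export
cohort_effect_defaults <- function() {
  df <- rbind(
    data.frame(metric = "Df",  region = c("whole", "inner_ring", "outer_ring"),
               base = c(1.387, 1.087, 1.312),
               b_sex = c(0.010, 0.030, 0.008),
               b_age = c(-9.812e-4, -2.069e-3, -7.904e-4),
               sd_tot = c(0.034, 0.085, 0.030)),
    data.frame(metric = "VAR", region = c("whole", "inner_ring", "outer_ring"),
               base = c(0.0135, 0.0020, 0.0116),
               b_sex = c(5.270e-4, 2.391e-4, 2.850e-4),
               b_age = c(-6.179e-5, -1.299e-5, -4.873e-5),
               sd_tot = c(0.0020, 0.0005, 0.0017)),
    data.frame(metric = "Dm",  region = c("whole", "inner_ring", "outer_ring"),
               base = c(0.146, 0.115, 0.151),
               b_sex = c(4.383e-4, 0.005, -4.312e-4),
               b_age = c(-2.710e-4, -2.652e-4, -2.684e-4),
               sd_tot = c(0.013, 0.016, 0.014)),
    data.frame(metric = "tau", region = c("whole", "inner_ring", "outer_ring"),
               base = c(2.765, 2.938, 2.707),
               b_sex = 0, b_age = 0,
               sd_tot = c(0.152, 0.359, 0.171))
  )
  df$base <- df$base - df$b_age * 33  # re-anchor to age 0 for the linear predictor
  df
}

#' Parameters for the synthetic paired-eye cohort generator
#'
#' Each metric-region column is drawn from the linear mixed structure
#' `value = b0 + b_sex * male + b_age * age + b_subject + e_eye` with
#' `b_subject ~ N(0, sd_b^2)` shared by both eyes of a subject and
#' `e_eye ~ N(0, sd_e^2)` independent per eye, giving intereye correlation
#' `sd_b^2 / (sd_b^2 + sd_e^2)`.
#'
#' @param n_subjects number of subjects; every subject contributes two eyes.
#' @param male_fraction fraction of male subjects (default 136/305, the
#'   study's ratio).
#' @param age_range ages drawn uniformly on this interval (years; default
#'   18--70, the study's inclusion window; uniform rather than the study's
#'   young-skewed mix, for better identification of the age slope).
#' @param intereye_cor intereye correlation of each metric (default 0.5).
#' @param effects data frame with columns `metric, region, base, b_sex,
#'   b_age, sd_tot`; defaults to [cohort_effect_defaults()].
#' @param noise_scale multiplies all SDs; `0` gives the noise-free limit in
#'   which every value equals its linear predictor exactly.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 305, male_fraction = 136 / 305,
                          age_range = c(18, 70), intereye_cor = 0.5,
                          effects = cohort_effect_defaults(),
                          noise_scale = 1) {
  if (n_subjects < 1) stop_validation("n_subjects must be >= 1")
  if (male_fraction < 0 || male_fraction > 1)
    stop_validation("male_fraction must be in [0, 1]")
  if (intereye_cor < 0 || intereye_cor > 1)
    stop_validation("intereye_cor must be in [0, 1]")
  if (noise_scale < 0) stop_validation("noise_scale must be >= 0")
  need <- c("metric", "region", "base", "b_sex", "b_age", "sd_tot")
  if (!all(need %in% names(effects)))
    stop_validation("effects must have columns ", paste(need, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 male_fraction = male_fraction, age_range = age_range,
                 intereye_cor = intereye_cor, effects = effects,
                 noise_scale = noise_scale),
            class = "cohort_params")
}

#' Generate a synthetic eye-level cohort table
#'
#' Draws `n_subjects` subjects (sex by the configured ratio, age uniform on
#' the configured range), two eyes each, and one column per metric x region
#' from the linear mixed structure described in [cohort_params()].
#'
#' @param params a [cohort_params()].
#' @param seed RNG seed; the table is a pure function of `(params, seed)`.
#' @return A data frame with `2 * n_subjects` rows and columns `subject_id`,
#'   `eye` (`OD`/`OS`), `sex` (`M`/`F`), `age_years`, then
#'   `<metric>_<region>` value columns.
#' @examples
#' tab <- generate_cohort(cohort_params(n_subjects = 20), seed = 1)
#' nrow(tab)  # 40 eyes
#' @export
generate_cohort <- function(params, seed = 1L) {
  if (!inherits(params, "cohort_params")) stop_validation("params must be cohort_params")
  with_seed(seed, {
    n <- params$n_subjects
    n_male <- round(n * params$male_fraction)
    sex <- sample(c(rep("M", n_male), rep("F", n - n_male)))
    age <- stats::runif(n, params$age_range[1], params$age_range[2])
    tab <- data.frame(
      subject_id = rep(sprintf("S%04d", seq_len(n)), each = 2),
      eye = rep(c("OD", "OS"), n),
      sex = rep(sex, each = 2),
      age_years = rep(age, each = 2),
      stringsAsFactors = FALSE)
    eff <- params$effects
    rho <- params$intereye_cor
    for (i in seq_len(nrow(eff))) {
      sd_tot <- eff$sd_tot[i] * params$noise_scale
      sd_b <- sd_tot * sqrt(rho)
      sd_e <- sd_tot * sqrt(1 - rho)
      mu <- eff$base[i] + eff$b_sex[i] * (sex == "M") + eff$b_age[i] * age
      b_subj <- stats::rnorm(n, 0, sd_b)
      vals <- rep(mu + b_subj, each = 2) + stats::rnorm(2 * n, 0, sd_e)
      tab[[paste(eff$metric[i], eff$region[i], sep = "_")]] <- vals
    }
    tab
  })
}
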