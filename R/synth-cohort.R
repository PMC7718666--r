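octa_metrics <- c("vd_scp", "vd_dcp", "fd_scp", "fd_dcp",
                  "pd_large_scp", "faz_area_scp", "faz_area_dcp")
cohort_groups <- c("control", "MCI", "AD")

#' Parameters for a synthetic AD/MCI/control cohort
#'
#' Defaults emulate a memory-clinic case-control cohort: group sizes 24 AD /
#' 37 MCI / 29 controls; per-group age, blood pressure, scan signal
#' strength, diabetes prevalence, sex and race composition; control-group
#' OCTA metric baselines; and additive group effects on each metric
#' (control offsets are zero by definition). Metric values are generated as
#' baseline + group offset + covariate terms (covariates centered at the
#' pooled means, so the baseline is also the expected covariate-adjusted
#' control mean) + Gaussian residual noise.
#'
#' @param n_per_group Named counts for `AD`, `MCI`, `control`.
#' @param age_mean,age_sd Per-group age distributions (years).
#' @param frac_female,frac_chinese,diabetes_prev Per-group probabilities.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd Blood pressure (mmHg).
#' @param signal_mean,signal_sd OCTA signal strength (0-10 scale, clamped).
#' @param mmse_mean,mmse_sd Cognitive screen score (0-30, clamped).
#' @param metric_baseline Control-group expected value per OCTA metric.
#' @param group_effects Metrics x (MCI, AD) matrix of additive offsets.
#' @param residual_sd Residual SD per metric (all > 0).
#' @param covariate_effects Metrics x covariates matrix of slopes applied to
#'   centered covariates (columns `age`, `female`, `chinese`, `diabetes`,
#'   `sbp`, `dbp`, `signal_strength`).
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(
    n_per_group = c(AD = 24L, MCI = 37L, control = 29L),
    age_mean = c(AD = 74.9, MCI = 77.9, control = 76.7),
    age_sd = c(AD = 6.0, MCI = 6.4, control = 5.3),
    frac_female = c(AD = 0.73, MCI = 0.44, control = 0.45),
    frac_chinese = c(AD = 0.84, MCI = 0.82, control = 0.79),
    diabetes_prev = c(AD = 0.41, MCI = 0.32, control = 0.14),
    sbp_mean = c(AD = 148, MCI = 139, control = 131),
    sbp_sd = c(AD = 11, MCI = 18, control = 16),
    dbp_mean = c(AD = 73, MCI = 70, control = 70),
    dbp_sd = c(AD = 9, MCI = 9, control = 8),
    signal_mean = c(AD = 9.8, MCI = 9.8, control = 9.6),
    signal_sd = c(AD = 0.8, MCI = 0.5, control = 0.7),
    mmse_mean = c(AD = 20.3, MCI = 23.9, control = 24.8),
    mmse_sd = c(AD = 6.1, MCI = 6.3, control = 4.8),
    metric_baseline = c(vd_scp = 15.66, vd_dcp = 21.54,
                        fd_scp = 1.861, fd_dcp = 1.879,
                        pd_large_scp = 6.92,
                        faz_area_scp = 0.31, faz_area_dcp = 1.11),
    group_effects = default_group_effects(),
    residual_sd = c(vd_scp = 0.96, vd_dcp = 1.55,
                    fd_scp = 0.010, fd_dcp = 0.013,
                    pd_large_scp = 1.16,
                    faz_area_scp = 0.12, faz_area_dcp = 0.47),
    covariate_effects = default_covariate_effects(),
    seed = 1L) {
  for (p in list(frac_female, frac_chinese, diabetes_prev)) {
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_per_group <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (any(residual_sd <= 0)) stop("residual SDs must be positive", call. = FALSE)
  if (!all(octa_metrics %in% names(metric_baseline)) ||
      !all(octa_metrics %in% rownames(group_effects)) ||
      !all(octa_metrics %in% names(residual_sd))) {
    stop("metric parameters must cover: ", paste(octa_metrics, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, age_mean = age_mean, age_sd = age_sd,
         frac_female = frac_female, frac_chinese = frac_chinese,
         diabetes_prev = diabetes_prev,
         sbp_mean = sbp_mean, sbp_sd = sbp_sd,
         dbp_mean = dbp_mean, dbp_sd = dbp_sd,
         signal_mean = signal_mean, signal_sd = signal_sd,
         mmse_mean = mmse_mean, mmse_sd = mmse_sd,
         metric_baseline = metric_baseline,
         group_effects = group_effects, residual_sd = residual_sd,
         covariate_effects = covariate_effects, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' @rdname cohort_params
#' @export
default_group_effects <- function() {
  m <- rbind(
    vd_scp       = c(MCI = -0.72,  AD = -0.88),
    vd_dcp       = c(MCI = -0.73,  AD = -1.12),
    fd_scp       = c(MCI = -0.011, AD = -0.008),
    fd_dcp       = c(MCI = -0.003, AD = -0.004),
    pd_large_scp = c(MCI = -0.53,  AD = 0.10),
    faz_area_scp = c(MCI = 0.041,  AD = 0.034),
    faz_area_dcp = c(MCI = 0.129,  AD = 0.016)
  )
  m
}

#' @rdname cohort_params
#' @export
default_covariate_effects <- function() {
  covs <- c("age", "female", "chinese", "diabetes", "sbp", "dbp",
            "signal_strength")
  m <- matrix(0, length(octa_metrics), length(covs),
              dimnames = list(octa_metrics, covs))
  # modest, plausible confounding: density falls with age and diabetes and
  # tracks scan quality; complexity follows density at its own scale
  m["vd_scp", c("age", "diabetes", "signal_strength")] <- c(-0.03, -0.30, 0.25)
  m["vd_dcp", c("age", "diabetes", "signal_strength")] <- c(-0.04, -0.40, 0.30)
  m["fd_scp", c("age", "signal_strength")] <- c(-3e-4, 2.5e-3)
  m["fd_dcp", c("age", "signal_strength")] <- c(-3e-4, 2.5e-3)
  m["pd_large_scp", "sbp"] <- -0.01
  m
}

#' Generate a synthetic cohort with known generating effects
#'
#' Draws one row per participant (group, covariates, two eyes' signal
#' strengths, OCTA metric values) from [cohort_params()], and returns the
#' true generating coefficients alongside so downstream regression stages
#' can be validated against them.
#'
#' @param params A [cohort_params()] object.
#' @return A list with `cohort` (data frame of class `cohort_table`) and
#'   `truth` (list with `group_effects`, `covariate_effects`,
#'   `metric_baseline`, `residual_sd`, and the pooled `covariate_centers`
#'   used for centering).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_per_group
  with_seed(params$seed, {
    groups <- factor(rep(cohort_groups, times = n[cohort_groups]),
                     levels = cohort_groups)
    N <- length(groups)
    g <- as.character(groups)
    age <- stats::rnorm(N, params$age_mean[g], params$age_sd[g])
    female <- stats::rbinom(N, 1L, params$frac_female[g])
    chinese <- stats::rbinom(N, 1L, params$frac_chinese[g])
    diabetes <- stats::rbinom(N, 1L, params$diabetes_prev[g])
    sbp <- stats::rnorm(N, params$sbp_mean[g], params$sbp_sd[g])
    dbp <- stats::rnorm(N, params$dbp_mean[g], params$dbp_sd[g])
    signal <- pmin(10, pmax(0, stats::rnorm(N, params$signal_mean[g],
                                            params$signal_sd[g])))
    mmse <- pmin(30, pmax(0, stats::rnorm(N, params$mmse_mean[g],
                                          params$mmse_sd[g])))
    # pooled expected covariate profile, for centering
    w <- n[cohort_groups] / sum(n)
    centers <- c(
      age = sum(w * params$age_mean[cohort_groups]),
      female = sum(w * params$frac_female[cohort_groups]),
      chinese = sum(w * params$frac_chinese[cohort_groups]),
      diabetes = sum(w * params$diabetes_prev[cohort_groups]),
      sbp = sum(w * params$sbp_mean[cohort_groups]),
      dbp = sum(w * params$dbp_mean[cohort_groups]),
      signal_strength = sum(w * params$signal_mean[cohort_groups])
    )
    X <- cbind(age = age - centers["age"],
               female = female - centers["female"],
               chinese = chinese - centers["chinese"],
               diabetes = diabetes - centers["diabetes"],
               sbp = sbp - centers["sbp"],
               dbp = dbp - centers["dbp"],
               signal_strength = signal - centers["signal_strength"])
    cohort <- data.frame(
      participant_id = sprintf("P%03d", seq_len(N)),
      group = groups,
      age = age,
      gender = factor(ifelse(female == 1L, "female", "male"),
                      levels = c("male", "female")),
      race = factor(ifelse(chinese == 1L, "Chinese", "other"),
                    levels = c("other", "Chinese")),
      diabetes = diabetes,
      sbp = sbp, dbp = dbp,
      signal_strength = signal,
      mmse = mmse,
      eye = sample(c("OD", "OS"), N, replace = TRUE),
      stringsAsFactors = FALSE
    )
    eff <- params$covariate_effects[, colnames(X), drop = FALSE]
    for (metric in octa_metrics) {
      offs <- c(control = 0, params$group_effects[metric, c("MCI", "AD")])
      cohort[[metric]] <- params$metric_baseline[[metric]] +
        offs[g] +
        as.numeric(X %*% eff[metric, ]) +
        stats::rnorm(N, 0, params$residual_sd[[metric]])
    }
    class(cohort) <- c("cohort_table", class(cohort))
    list(cohort = cohort,
         truth = list(group_effects = params$group_effects,
                      covariate_effects = eff,
                      metric_baseline = params$metric_baseline,
                      residual_sd = params$residual_sd,
                      covariate_centers = centers))
  })
}
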