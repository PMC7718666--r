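#' Apply participant eligibility filters
#'
#' A participant is excluded if they could not complete scanning (fatigue),
#' if every scanned eye fails the quality floor (signal strength below
#' `min_signal`), or if eye disease is present. Exclusion reasons are
#' tallied with a fixed precedence -- fatigue, then quality, then eye
#' disease -- so each excluded participant is counted once under the first
#' matching reason and the tally sums to enrolled minus included.
#'
#' @param enrolled Data frame with logical columns `fatigue` and
#'   `eye_disease`, and per-eye signal strengths `signal_strength_od`,
#'   `signal_strength_os` (`NA` for an unscanned eye).
#' @param min_signal Quality floor on the 0-10 signal-strength scale
#'   (default 7; scans below it are poor quality).
#' @return A list with `included` (the retained rows), `tally` (named
#'   exclusion counts), `n_enrolled`, and `n_included`.
#' @export
apply_eligibility_filters <- function(enrolled, min_signal = 7) {
  required <- c("fatigue", "eye_disease", "signal_strength_od", "signal_strength_os")
  missing_cols <- setdiff(required, names(enrolled))
  if (length(missing_cols)) {
    stop("eligibility flags missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ss <- cbind(enrolled$signal_strength_od, enrolled$signal_strength_os)
  scanned <- !is.na(ss)
  any_good <- rowSums(scanned & ss >= min_signal, na.rm = TRUE) > 0
  quality_fail <- !any_good
  fatigue <- as.logical(enrolled$fatigue)
  disease <- as.logical(enrolled$eye_disease)
  if (any(is.na(fatigue)) || any(is.na(disease))) {
    stop("eligibility flags contain missing values", call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(enrolled))
  reason[disease] <- "eye_disease"
  reason[quality_fail] <- "quality"
  reason[fatigue] <- "fatigue"          # highest precedence applied last
  included <- enrolled[is.na(reason), , drop = FALSE]
  tally <- c(fatigue = sum(reason == "fatigue", na.rm = TRUE),
             quality = sum(reason == "quality", na.rm = TRUE),
             eye_disease = sum(reason == "eye_disease", na.rm = TRUE))
  list(included = included, tally = tally,
       n_enrolled = nrow(enrolled), n_included = nrow(included))
}

#' Randomly select the analysis eye
#'
#' One eye is analyzed per participant; among eligible eyes the choice is
#' uniform and deterministic for a given seed. A single eligible eye is
#' returned directly.
#'
#' @param eyes Character vector of eligible eye labels (e.g. `c("OD","OS")`).
#' @param seed Integer seed.
#' @return One eye label.
#' @export
select_analysis_eye <- function(eyes, seed) {
  eyes <- as.character(eyes)
  if (length(eyes) < 1L) stop("no eligible eye to select", call. = FALSE)
  if (length(eyes) == 1L) return(eyes)
  with_seed(seed, eyes[sample.int(length(eyes), 1L)])
}

#' Baseline group comparison of one characteristic
#'
#' One-way ANOVA for continuous variables; Pearson chi-square (without
#' continuity correction) for categorical ones. A variable that is constant
#' within and between groups yields F = 0 with p = 1 rather than an error.
#'
#' @param cohort Data frame with a `group` column.
#' @param variable Column name to compare.
#' @param group_col Grouping column (default `"group"`).
#' @return A list with `variable`, `type` (`"anova"` or `"chisq"`),
#'   `statistic`, `df`, and `p_value`.
#' @export
baseline_comparison <- function(cohort, variable, group_col = "group") {
  if (!variable %in% names(cohort)) {
    stop("no such column: ", variable, call. = FALSE)
  }
  x <- cohort[[variable]]
  gr <- factor(cohort[[group_col]])
  if (nlevels(droplevels(gr)) < 2L) stop("need at least two groups", call. = FALSE)
  if (is.numeric(x)) {
    if (stats::var(x) < 1e-24) {
      return(list(variable = variable, type = "anova", statistic = 0,
                  df = c(nlevels(gr) - 1L, length(x) - nlevels(gr)),
                  p_value = 1))
    }
    fit <- stats::aov(x ~ gr)
    s <- summary(fit)[[1L]]
    list(variable = variable, type = "anova",
         statistic = s[["F value"]][1L],
         df = s[["Df"]],
         p_value = s[["Pr(>F)"]][1L])
  } else {
    tab <- table(factor(x), gr)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p <- ct$p.value
    stat <- unname(ct$statistic)
    if (is.nan(stat)) { stat <- 0; p <- 1 }   # constant categorical
    list(variable = variable, type = "chisq", statistic = stat,
         df = unname(ct$parameter), p_value = p)
  }
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param k_outcomes Number of outcomes in the family.
#' @return `alpha / k_outcomes`.
#' @export
bonferroni_threshold <- function(alpha, k_outcomes) {
  stop_if_not_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  stop_if_not_scalar_number(k_outcomes, "k_outcomes", lower = 1)
  alpha / k_outcomes
}

#' Covariate-adjusted group comparison by multivariable linear regression
#'
#' Fits `outcome ~ group + covariates` by least squares with the control
#' group as reference, and reports per-group coefficients (beta, confidence
#' interval, two-sided t-test p-value) plus adjusted group means: model
#' predictions at the pooled sample-mean covariate profile (categorical
#' covariates at their sample proportions, i.e. proportionally weighted
#' estimated marginal means). By construction the adjusted-mean difference
#' between a group and control equals that group's beta exactly.
#'
#' @param cohort Data frame with `group` and the covariate columns.
#' @param outcome Outcome column name.
#' @param covariates Character vector of adjustment covariates.
#' @param group_col Grouping column; must contain a `"control"` level.
#' @param conf_level Confidence level for the CIs.
#' @return A list of class `adjusted_model_result` with `outcome`, `n`,
#'   `groups` (data frame: group, adjusted_mean, se, raw_sd, n), `betas`
#'   (data frame: group, estimate, ci_lower, ci_upper, p_value),
#'   `covariates` (coefficient table), and `sigma` (residual scale).
#' @export
fit_adjusted_model <- function(cohort, outcome,
                               covariates = c("age", "gender", "race",
                                              "diabetes", "sbp", "dbp",
                                              "signal_strength"),
                               group_col = "group", conf_level = 0.95) {
  missing_cols <- setdiff(c(outcome, covariates, group_col), names(cohort))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- cohort[, c(outcome, group_col, covariates)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  gr <- factor(dat[[group_col]])
  if (!"control" %in% levels(gr)) stop("no 'control' group present", call. = FALSE)
  gr <- stats::relevel(gr, ref = "control")
  dat$.group <- gr
  fml <- stats::reformulate(c(".group", covariates), response = outcome)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- stats::coef(fit)
  ci <- stats::confint(fit, level = conf_level)
  sm <- summary(fit)$coefficients
  mm <- stats::model.matrix(fit)
  xbar <- colMeans(mm)
  grp_cols <- grep("^\\.group", colnames(mm), value = TRUE)
  lev <- levels(gr)
  adj <- vapply(lev, function(g) {
    row <- xbar
    row[grp_cols] <- 0
    if (g != "control") row[paste0(".group", g)] <- 1
    sum(row * cf)
  }, numeric(1))
  adj_se <- vapply(lev, function(g) {
    row <- xbar
    row[grp_cols] <- 0
    if (g != "control") row[paste0(".group", g)] <- 1
    sqrt(drop(t(row) %*% stats::vcov(fit) %*% row))
  }, numeric(1))
  raw_sd <- vapply(lev, function(g) stats::sd(dat[[outcome]][gr == g]), numeric(1))
  n_g <- vapply(lev, function(g) sum(gr == g), numeric(1))
  non_ref <- setdiff(lev, "control")
  betas <- data.frame(
    group = non_ref,
    estimate = cf[paste0(".group", non_ref)],
    ci_lower = ci[paste0(".group", non_ref), 1L],
    ci_upper = ci[paste0(".group", non_ref), 2L],
    p_value = sm[paste0(".group", non_ref), "Pr(>|t|)"],
    row.names = NULL
  )
  cov_rows <- setdiff(rownames(sm), c("(Intercept)", paste0(".group", non_ref)))
  structure(
    list(outcome = outcome, n = nrow(dat),
         groups = data.frame(group = lev, adjusted_mean = adj, se = adj_se,
                             raw_sd = raw_sd, n = n_g, row.names = NULL),
         betas = betas,
         covariates = as.data.frame(sm[cov_rows, , drop = FALSE]),
         sigma = summary(fit)$sigma,
         conf_level = conf_level),
    class = "adjusted_model_result"
  )
}

#' @export
print.adjusted_model_result <- function(x, ...) {
  cat(sprintf("<adjusted_model_result> outcome %s, n = %d\n", x$outcome, x$n))
  print(x$groups, digits = 4)
  print(x$betas, digits = 4)
  invisible(x)
}

#' Post hoc power for a two-group mean comparison
#'
#' Normal-approximation power of the unequal-variance two-sample z test:
#' \deqn{power = \Phi(|\Delta| / \sqrt{s_1^2/n_1 + s_2^2/n_2} - z_{1-\alpha/2}).}
#' At \eqn{\Delta = 0} this equals \eqn{\alpha/2}, the one-sided rejection
#' rate of the two-sided test.
#'
#' @param mean1,sd1,n1 First group summary (SD > 0, n >= 2).
#' @param mean2,sd2,n2 Second group summary.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
posthoc_power <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  stop_if_not_scalar_number(sd1, "sd1", lower = 1e-12)
  stop_if_not_scalar_number(sd2, "sd2", lower = 1e-12)
  stop_if_not_scalar_number(n1, "n1", lower = 2)
  stop_if_not_scalar_number(n2, "n2", lower = 2)
  stop_if_not_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  stats::pnorm(abs(mean1 - mean2) / se - stats::qnorm(1 - alpha / 2))
}
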