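test_that("eligibility filtering reproduces the enrolment flow", {
  enr <- make_enrolled()
  res <- apply_eligibility_filters(enr)
  expect_equal(res$n_enrolled, 165L)
  expect_equal(res$n_included, 90L)
  expect_equal(unname(res$tally), c(15L, 53L, 7L))
  expect_equal(sum(res$tally), res$n_enrolled - res$n_included)
  # no flags set: everyone included
  clean <- make_enrolled(0, 0, 0, 20)
  expect_equal(apply_eligibility_filters(clean)$n_included, 20L)
  # both eyes below the signal floor: excluded under quality
  one <- data.frame(fatigue = FALSE, eye_disease = FALSE,
                    signal_strength_od = 6, signal_strength_os = 6)
  r1 <- apply_eligibility_filters(one)
  expect_equal(r1$n_included, 0L)
  expect_equal(unname(r1$tally["quality"]), 1L)
  # one good eye rescues the participant
  one$signal_strength_os <- 7
  expect_equal(apply_eligibility_filters(one)$n_included, 1L)
  expect_error(apply_eligibility_filters(data.frame(fatigue = FALSE)),
               "eye_disease")
})

test_that("analysis-eye selection is uniform and seed-deterministic", {
  expect_equal(select_analysis_eye("OD", seed = 1), "OD")
  expect_identical(select_analysis_eye(c("OD", "OS"), seed = 42),
                   select_analysis_eye(c("OD", "OS"), seed = 42))
  expect_error(select_analysis_eye(character(0), seed = 1), "eligible")
  frac_os <- mean(vapply(1:10000,
                         function(i) select_analysis_eye(c("OD", "OS"), i) == "OS",
                         logical(1)))
  expect_equal(frac_os, 0.5, tolerance = 0.02 / 0.5)
})

test_that("baseline comparisons match textbook ANOVA and chi-square results", {
  dat <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                    x = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
  r <- baseline_comparison(dat, "x")
  # SSB = 42 on 2 df, SSW = 6 on 6 df -> F = 21
  expect_equal(r$statistic, 21)
  expect_equal(r$p_value, pf(21, 2, 6, lower.tail = FALSE))
  # identical groups: F near 0 impossible exactly, use constant case
  const <- data.frame(group = rep(c("a", "b"), each = 3), x = rep(1, 6))
  rc <- baseline_comparison(const, "x")
  expect_equal(rc$statistic, 0)
  expect_equal(rc$p_value, 1)
  # balanced 2x3 table: chi-square 0, p 1
  tabdat <- data.frame(group = rep(c("a", "b", "c"), each = 20),
                       x = factor(rep(rep(c("y", "n"), each = 10), 3)))
  rt <- baseline_comparison(tabdat, "x")
  expect_equal(rt$type, "chisq")
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 1)
})

test_that("bonferroni threshold divides alpha by the family size", {
  expect_identical(bonferroni_threshold(0.05, 2), 0.025)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.06, 3), 0.02)
  expect_error(bonferroni_threshold(1.2, 2), "alpha")
})

test_that("noise-free group offsets are recovered to machine precision", {
  set.seed(3)
  n <- 30
  gr <- rep(c("control", "MCI", "AD"), each = n)
  age <- runif(3 * n, 60, 90)
  sbp <- runif(3 * n, 110, 160)
  offs <- c(control = 0, MCI = -0.5, AD = -1.0)
  y <- 15 + offs[gr] - 0.02 * age + 0.01 * sbp
  dat <- data.frame(group = gr, age = age, sbp = sbp, y = y)
  fit <- suppressWarnings(  # lm flags the intentionally perfect fit
    fit_adjusted_model(dat, "y", covariates = c("age", "sbp")))
  b <- setNames(fit$betas$estimate, fit$betas$group)
  expect_equal(unname(b["MCI"]), -0.5, tolerance = 1e-10)
  expect_equal(unname(b["AD"]), -1.0, tolerance = 1e-10)
})

test_that("beta equals the adjusted-mean difference on arbitrary data", {
  g <- generate_cohort(cohort_params(seed = 31))
  for (outcome in c("vd_scp", "fd_dcp", "faz_area_scp")) {
    fit <- fit_adjusted_model(g$cohort, outcome)
    am <- setNames(fit$groups$adjusted_mean, fit$groups$group)
    b <- setNames(fit$betas$estimate, fit$betas$group)
    expect_equal(unname(am["MCI"] - am["control"]), unname(b["MCI"]),
                 tolerance = 1e-12)
    expect_equal(unname(am["AD"] - am["control"]), unname(b["AD"]),
                 tolerance = 1e-12)
  }
})

test_that("adjusted means agree with proportionally weighted marginal means", {
  skip_if_not_installed("emmeans")
  g <- generate_cohort(cohort_params(seed = 17))
  fit <- fit_adjusted_model(g$cohort, "vd_scp")
  co <- g$cohort
  co$group <- relevel(factor(co$group), "control")
  ref <- lm(vd_scp ~ group + age + gender + race + diabetes + sbp + dbp +
              signal_strength, co)
  em <- summary(emmeans::emmeans(ref, "group", weights = "proportional"))
  am <- setNames(fit$groups$adjusted_mean, fit$groups$group)
  expect_equal(unname(am[as.character(em$group)]), em$emmean, tolerance = 1e-8)
})

test_that("collinear designs fail with the offending column named", {
  g <- generate_cohort(cohort_params(seed = 5))
  co <- g$cohort
  co$sbp_copy <- co$sbp
  expect_error(fit_adjusted_model(co, "vd_scp",
                                  covariates = c("age", "sbp", "sbp_copy")),
               "sbp_copy")
})

test_that("post hoc power follows the normal-approximation formula", {
  expect_equal(posthoc_power(30.54, 2.86, 24, 32.60, 2.36, 29), 0.805,
               tolerance = 0.005 / 0.805)
  expect_gte(posthoc_power(43.5, 4.0, 24, 50.9, 3.6, 29), 0.999)
  # null limit: power equals alpha / 2 exactly
  expect_equal(posthoc_power(10, 2, 20, 10, 2, 20, alpha = 0.05), 0.025)
  # monotone in effect size and sample size
  p1 <- posthoc_power(10, 2, 20, 11, 2, 20)
  p2 <- posthoc_power(10, 2, 20, 12, 2, 20)
  p3 <- posthoc_power(10, 2, 40, 11, 2, 40)
  expect_gt(p2, p1)
  expect_gt(p3, p1)
  expect_error(posthoc_power(1, 0, 10, 2, 1, 10), "sd1")
})
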