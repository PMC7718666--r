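test_that("empty scene yields a blank image with zero skeleton length", {
  p <- angio_scene_params(capillary_density = 0, n_large_vessels = 0,
                          faz_area_mm2 = 0.31, seed = 1)
  tr <- generate_vessel_network(p)
  expect_equal(tr$skeleton_length_mm, 0)
  expect_false(any(tr$vessel_mask))
  expect_false(any(tr$large_vessel_mask))
  expect_false(any(tr$skeleton_mask))
})

test_that("a straight horizontal vessel spanning the field has the analytic length", {
  ctr <- 1.5
  sc <- render_vessel_scene(list(cbind(c(0, 3), c(ctr, ctr))), widths_px = 5)
  expect_equal(sc$skeleton_length_mm, 3.0, tolerance = 1e-12)
  # counted on the rendered raster: one centerline pixel per column
  expect_equal(sum(sc$skeleton_mask) * scan_mpp, 3.0, tolerance = 0.01)
  # rendered width within 1 px of the configured width at mid-vessel
  widths <- colSums(sc$vessel_mask[, 60:180])
  expect_true(all(abs(widths - 5) <= 1))
})

test_that("identical seeds give bitwise-identical scenes", {
  p <- angio_scene_params(seed = 99)
  a <- generate_vessel_network(p)
  b <- generate_vessel_network(p)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$vessel_mask, b$vessel_mask)
  expect_identical(a$faz_polygon, b$faz_polygon)
  c <- generate_vessel_network(angio_scene_params(seed = 100))
  expect_false(identical(a$image$intensities, c$image$intensities))
})

test_that("stored skeleton length matches the generating centerlines and FAZ hits its target area", {
  for (sd in c(2, 5)) {
    tr <- generate_vessel_network(angio_scene_params(seed = sd))
    analytic <- sum(vapply(tr$centerlines, function(v) {
      xy <- v$xy
      sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
    }, numeric(1)))
    expect_equal(tr$skeleton_length_mm, analytic, tolerance = 0.01)
    expect_equal(faz_area(tr$faz_polygon), tr$params$faz_area_mm2,
                 tolerance = 0.05)
    # FAZ interior carries no vessel pixels
    inside <- octaquant:::faz_interior_mask(tr$faz_polygon, 245, scan_mpp)
    expect_false(any(tr$vessel_mask & inside))
    expect_true(all(tr$vessel_mask[tr$large_vessel_mask]))
  }
})

test_that("DCP-style scenes are mesh-only with the larger FAZ", {
  p <- angio_scene_params(plexus = "DCP", seed = 3)
  expect_equal(p$n_large_vessels, 0L)
  expect_equal(p$faz_area_mm2, 1.11)
  tr <- generate_vessel_network(p)
  expect_false(any(tr$large_vessel_mask))
  expect_equal(tr$image$plexus, "DCP")
})

test_that("degenerate scene parameters are rejected", {
  expect_error(angio_scene_params(grid_px = 16), "grid_px")
  expect_error(angio_scene_params(capillary_density = -1), "capillary_density")
  # grid too small to render the requested large-vessel width
  p <- angio_scene_params(grid_px = 40, field_mm = 0.49,
                          large_width_um = c(60, 80), seed = 1)
  expect_error(generate_vessel_network(p), "too small")
})

test_that("cohort generator is deterministic and matches the configured moments", {
  p <- cohort_params(seed = 8)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$cohort, b$cohort)
  expect_equal(nrow(a$cohort), 90L)
  expect_equal(as.integer(table(a$cohort$group)[c("AD", "MCI", "control")]),
               c(24L, 37L, 29L))
  # default age distribution reproduces the configured cohort mean at n ~ 1000
  big <- generate_cohort(cohort_params(
    n_per_group = c(AD = 267L, MCI = 411L, control = 322L), seed = 2))
  expect_equal(mean(big$cohort$age), 76.8, tolerance = 0.5 / 76.8)
  expect_equal(mean(big$cohort$gender == "female"), 0.51, tolerance = 0.05)
})

test_that("null group effects produce near-zero fitted group coefficients", {
  eff <- default_group_effects() * 0
  g <- generate_cohort(cohort_params(
    n_per_group = c(AD = 300L, MCI = 300L, control = 300L),
    group_effects = eff, seed = 4))
  fit <- fit_adjusted_model(g$cohort, "vd_scp")
  for (i in seq_len(nrow(fit$betas))) {
    se <- (fit$betas$ci_upper[i] - fit$betas$ci_lower[i]) / (2 * 1.96)
    expect_lt(abs(fit$betas$estimate[i]), 2 * se)
  }
})

test_that("a planted AD effect is recovered inside its CI in most replicates", {
  p0 <- cohort_params(n_per_group = c(AD = 500L, MCI = 50L, control = 500L),
                      residual_sd = c(vd_scp = 1.0, vd_dcp = 1.55,
                                      fd_scp = 0.010, fd_dcp = 0.013,
                                      pd_large_scp = 1.16,
                                      faz_area_scp = 0.12, faz_area_dcp = 0.47))
  hits <- vapply(1:100, function(i) {
    p0$seed <- i
    g <- generate_cohort(p0)
    fit <- fit_adjusted_model(g$cohort, "vd_scp")
    b <- fit$betas[fit$betas$group == "AD", ]
    b$ci_lower <= -0.88 && -0.88 <= b$ci_upper
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("empirical covariate moments converge to the configured values", {
  g <- generate_cohort(cohort_params(
    n_per_group = c(AD = 2000L, MCI = 100L, control = 100L), seed = 6))
  ad <- g$cohort[g$cohort$group == "AD", ]
  expect_equal(mean(ad$age), 74.9, tolerance = 0.5 / 74.9)
  expect_equal(sd(ad$age), 6.0, tolerance = 0.1)
  expect_equal(mean(ad$diabetes), 0.41, tolerance = 0.05)
  expect_equal(mean(ad$sbp), 148, tolerance = 0.01)
})
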