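test_that("annulus mask area matches the analytic ring area", {
  ctr <- c(scan_centre, scan_centre)
  m <- annulus_mask(annulus_spec(ctr), c(245, 245), scan_mpp)
  area <- sum(m) * scan_mpp^2
  expect_equal(area, pi * (1.25^2 - 0.5^2), tolerance = 0.01)
  # membership at specific radii (half-open [inner, outer))
  px_at <- function(r_mm) {
    col <- round(ctr[1] / scan_mpp) + 1 + round(r_mm / scan_mpp)
    m[round(ctr[2] / scan_mpp) + 1, col]
  }
  expect_false(px_at(0.3))
  expect_true(px_at(0.6))
  expect_false(px_at(1.4))
})

test_that("annulus mask is translation-equivariant and errors outside the field", {
  ctr <- c(scan_centre, scan_centre)
  m0 <- annulus_mask(annulus_spec(ctr), c(245, 245), scan_mpp)
  d <- 5 * scan_mpp
  m1 <- annulus_mask(annulus_spec(ctr + c(d, 0)), c(245, 245), scan_mpp)
  expect_identical(m1[, 6:245], m0[, 1:240])
  expect_error(annulus_mask(annulus_spec(c(0.3, 1.5)), c(245, 245), scan_mpp),
               "fit")
})

test_that("annulus area converges to the analytic value with resolution", {
  n <- 980L  # 4x the standard sampling
  mpp <- 3 / n
  ctr <- rep((n - 1) / 2 * mpp, 2)
  area <- sum(annulus_mask(annulus_spec(ctr), c(n, n), mpp)) * mpp^2
  expect_equal(area, pi * (1.25^2 - 0.5^2), tolerance = 0.002)
})

test_that("polygon centroid and area follow the shoelace formulas", {
  sq <- faz_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(faz_center(sq), c(0.5, 0.5))
  expect_equal(faz_area(sq), 1.0)
  shifted <- faz_polygon(cbind(c(0, 1, 1, 0) + 2, c(0, 0, 1, 1) - 1))
  expect_equal(faz_center(shifted), c(2.5, -0.5))
  # L-shaped hexagon: two rectangles [0,2]x[0,1] and [0,1]x[1,2]
  ell <- faz_polygon(cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2)))
  expect_equal(faz_area(ell), 3)
  expect_equal(faz_center(ell), c(2.5 / 3, 2.5 / 3))
  # orientation invariance of area
  rev_sq <- faz_polygon(cbind(c(0, 1, 1, 0)[4:1], c(0, 0, 1, 1)[4:1]))
  expect_equal(faz_area(rev_sq), 1.0)
  # regular 64-gon of circumradius 0.5: (1/2) n R^2 sin(2 pi / n)
  p64 <- circle_polygon(c(0, 0), 0.5, 64L)
  expect_equal(faz_area(p64), 0.5 * 64 * 0.25 * sin(2 * pi / 64),
               tolerance = 1e-10)
})

test_that("measurement region removes only FAZ overlapping the annulus", {
  ctr <- c(scan_centre, scan_centre)
  ann <- annulus_mask(annulus_spec(ctr), c(245, 245), scan_mpp)
  # SCP-typical FAZ (r ~ 0.31 mm) sits inside the inner disk: no change
  small <- circle_polygon(ctr, sqrt(0.31 / pi))
  reg <- measurement_region(ann, small)
  expect_equal(sum(reg$mask), sum(ann))
  # circular FAZ of radius 0.6 mm removes the analytic ring overlap
  big <- circle_polygon(ctr, 0.6)
  reg2 <- measurement_region(ann, big)
  expect_equal(reg2$area_mm2, pi * (1.25^2 - 0.5^2) - pi * (0.6^2 - 0.5^2),
               tolerance = 0.01)
  # no polygon: region equals annulus, with a warning
  expect_warning(reg3 <- measurement_region(ann, NULL), "FAZ")
  expect_identical(sum(reg3$mask), sum(ann))
})

test_that("vessel density matches the analytic chord length through the annulus", {
  ctr <- c(scan_centre, scan_centre)
  ann <- annulus_mask(annulus_spec(ctr), c(245, 245), scan_mpp)
  reg <- suppressWarnings(measurement_region(ann, NULL))
  expect_equal(vessel_density(matrix(FALSE, 245, 245), reg), 0)
  # a straight horizontal chord through the centre crosses the annulus twice
  chord <- matrix(FALSE, 245, 245)
  chord[123, ] <- TRUE
  vd <- vessel_density(chord, reg)
  expect_equal(vd, 2 * (1.25 - 0.5) / (pi * (1.25^2 - 0.5^2)), tolerance = 0.05)
})

test_that("vessel density recovers generator ground truth within 5%", {
  for (sd in c(12, 27)) {
    tr <- generate_vessel_network(angio_scene_params(seed = sd))
    reg <- scene_region(tr)
    vd <- vessel_density(skeletonize(binarize(tr$image)), reg)
    truth <- scene_region_length(tr, reg) / reg$area_mm2
    expect_equal(vd, truth, tolerance = 0.05)
  }
})

test_that("perfusion density is the in-region areal fraction in percent", {
  ctr <- c(scan_centre, scan_centre)
  ann <- annulus_mask(annulus_spec(ctr), c(245, 245), scan_mpp)
  reg <- suppressWarnings(measurement_region(ann, NULL))
  expect_equal(large_vessel_perfusion_density(matrix(FALSE, 245, 245), reg), 0)
  expect_equal(large_vessel_perfusion_density(matrix(TRUE, 245, 245), reg), 100)
  band <- matrix(FALSE, 245, 245)
  band[100:110, ] <- TRUE
  f <- sum(band & reg$mask) / sum(reg$mask)
  expect_equal(large_vessel_perfusion_density(band, reg), 100 * f,
               tolerance = 1e-12)
})

test_that("box-counting dimension matches known sets", {
  reg <- full_frame_region(243)
  expect_equal(fractal_dimension_boxcount(matrix(TRUE, 243, 243), reg), 2.0,
               tolerance = 0.05 / 2)
  line <- matrix(FALSE, 243, 243); line[120, ] <- TRUE
  expect_equal(fractal_dimension_boxcount(line, reg), 1.0, tolerance = 0.05)
  expect_equal(fractal_dimension_boxcount(sierpinski_carpet(5), reg),
               log(8) / log(3), tolerance = 0.05 / 1.89)
  expect_error(fractal_dimension_boxcount(matrix(FALSE, 243, 243), reg),
               "foreground")
})

test_that("box counts are idempotent under self-union and VD is intensity-scale invariant", {
  reg <- full_frame_region(128)
  line <- matrix(FALSE, 128, 128); line[60, ] <- TRUE
  expect_identical(fractal_dimension_boxcount(line, reg),
                   fractal_dimension_boxcount(line | line, reg))
  sc <- render_vessel_scene(list(cbind(c(0.3, 2.7), c(1.5, 1.5))), widths_px = 4)
  ctr <- c(scan_centre, scan_centre)
  ann <- annulus_mask(annulus_spec(ctr), c(245, 245), scan_mpp)
  regA <- suppressWarnings(measurement_region(ann, NULL))
  vd1 <- vessel_density(skeletonize(binarize(sc$image$intensities), scan_mpp), regA)
  vd2 <- vessel_density(skeletonize(binarize(sc$image$intensities * 3), scan_mpp), regA)
  expect_identical(vd1, vd2)
})

test_that("the composite metric record is complete, symmetric, and NA-tolerant", {
  tr_scp <- generate_vessel_network(angio_scene_params(seed = 21))
  tr_dcp <- generate_vessel_network(angio_scene_params(plexus = "DCP", seed = 22))
  rec <- compute_metric_record(tr_scp$image, tr_dcp$image,
                               tr_scp$faz_polygon, tr_dcp$faz_polygon)
  expect_true(all(c("vd_scp", "vd_dcp", "fd_scp", "fd_dcp", "pd_large_scp",
                    "faz_area_scp", "faz_area_dcp") %in% names(rec)))
  expect_true(rec$vd_scp > 0 && rec$vd_dcp > 0)
  expect_true(rec$fd_scp > 0.9 && rec$fd_scp < 2.1)
  expect_true(rec$pd_large_scp >= 0 && rec$pd_large_scp <= 100)
  # identical SCP and DCP inputs give identical per-plexus VD and FD
  dcp_copy <- tr_scp$image
  dcp_copy$plexus <- "DCP"
  rec2 <- compute_metric_record(tr_scp$image, dcp_copy,
                                tr_scp$faz_polygon, tr_scp$faz_polygon)
  expect_identical(rec2$vd_scp, rec2$vd_dcp)
  expect_identical(rec2$fd_scp, rec2$fd_dcp)
  # missing DCP image: explicit NA fields
  rec3 <- compute_metric_record(tr_scp$image, scp_faz = tr_scp$faz_polygon)
  expect_true(is.na(rec3$vd_dcp) && is.na(rec3$fd_dcp) && is.na(rec3$faz_area_dcp))
})
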