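test_that("vesselness is zero on constant images and errors on empty scales", {
  m <- matrix(0.4, 64, 64)
  v <- hessian_vesselness(m)
  expect_true(all(v$responses == 0))
  expect_error(hessian_vesselness(m, scales_px = numeric(0)), "scale")
  expect_error(hessian_vesselness(m, scales_px = -1), "positive")
})

test_that("a bright tube responds strongly at its centerline and nearly isotropically", {
  sc <- render_vessel_scene(list(cbind(c(0, 3), c(1.5, 1.5))), widths_px = 4)
  v <- hessian_vesselness(sc$image)
  centre_resp <- median(v$responses[sc$skeleton_mask])
  bg99 <- quantile(v$responses[!sc$vessel_mask], 0.99)
  expect_gte(centre_resp, 5 * bg99)
  # same tube rotated 37 degrees: centerline response within 10%
  th <- 37 * pi / 180
  ends <- rbind(1.5 - 1.4 * c(cos(th), sin(th)), 1.5 + 1.4 * c(cos(th), sin(th)))
  rotated <- render_vessel_scene(list(ends), widths_px = 4)
  vr <- hessian_vesselness(rotated$image)
  rot_resp <- median(vr$responses[rotated$skeleton_mask])
  expect_equal(rot_resp, centre_resp, tolerance = 0.10)
})

test_that("binarization recovers noise-free two-level images exactly", {
  expect_false(any(binarize(matrix(0, 64, 64))$mask))
  tl <- matrix(0.2, 64, 64)
  tl[20:25, 10:50] <- 0.8
  tl[40:44, 30:34] <- 0.8
  expect_identical(binarize(tl)$mask, tl > 0.5)
})

test_that("binarization overlaps the truth mask under realistic noise", {
  set.seed(42)
  sc <- render_vessel_scene(list(cbind(c(0, 3), c(1.5, 1.5))), widths_px = 4,
                            noise_sd = 0.07)  # 10% of the 0.7 contrast
  bm <- binarize(sc$image)
  dice <- 2 * sum(bm$mask & sc$vessel_mask) /
    (sum(bm$mask) + sum(sc$vessel_mask))
  expect_gte(dice, 0.9)
})

test_that("large-vessel detection separates width classes on generated scenes", {
  p <- angio_scene_params(seed = 3, n_large_vessels = 2,
                          large_width_um = c(70, 75), capillary_density = 12)
  tr <- generate_vessel_network(p)
  lv <- detect_large_vessels(tr$image)
  coverage <- sum(lv$mask & tr$large_vessel_mask) / sum(tr$large_vessel_mask)
  caps <- tr$vessel_mask & !tr$large_vessel_mask
  leak <- sum(lv$mask & caps) / sum(caps)
  expect_gte(coverage, 0.90)
  expect_lte(leak, 0.05)
})

test_that("a capillaries-only scene yields an empty large-vessel mask", {
  tr <- generate_vessel_network(angio_scene_params(seed = 4, n_large_vessels = 0))
  expect_false(any(detect_large_vessels(tr$image)$mask))
})

test_that("the fraction classified large is non-decreasing in vessel width", {
  frac <- vapply(c(2, 4, 6, 8), function(w) {
    sc <- render_vessel_scene(list(cbind(c(0, 3), c(1.0, 1.0)),
                                   cbind(c(0, 3), c(2.0, 2.2))),
                              widths_px = c(w, 1.5))
    lv <- detect_large_vessels(sc$image)
    wide <- sc$vessel_mask & row(sc$vessel_mask) < 123
    sum(lv$mask & wide) / sum(wide)
  }, numeric(1))
  expect_true(all(diff(frac) >= -1e-9))
})

test_that("large-vessel detection refuses DCP images", {
  tr <- generate_vessel_network(angio_scene_params(plexus = "DCP", seed = 2))
  expect_error(detect_large_vessels(tr$image), "SCP")
})

test_that("skeletonization recovers bar lengths and is idempotent", {
  mpp <- 3 / 245
  expect_equal(skeletonize(matrix(FALSE, 64, 64), mpp)$length_mm, 0)
  bar <- matrix(FALSE, 245, 245)
  bar[120:124, 50:149] <- TRUE  # 100 px long, 5 px wide
  sk <- skeletonize(bar, mm_per_pixel = mpp)
  expect_equal(sk$length_mm, 100 * mpp, tolerance = 0.03)
  # same bar along the diagonal: sqrt(2) x the orthogonal step count
  dg <- matrix(FALSE, 245, 245)
  for (o in -2:2) {
    idx <- 50:149
    dg[cbind(idx + o, idx)] <- TRUE
    dg[cbind(idx, idx + o)] <- TRUE
  }
  skd <- skeletonize(dg, mm_per_pixel = mpp)
  expect_equal(skd$length_mm, 99 * sqrt(2) * mpp, tolerance = 0.03)
  # idempotence
  expect_identical(skeletonize(sk$skeleton)$skeleton, sk$skeleton)
  expect_identical(skeletonize(skd$skeleton)$skeleton, skd$skeleton)
})

test_that("skeleton length counts each adjacency once with the triangle rule", {
  mpp <- 0.01
  one <- matrix(FALSE, 40, 40); one[5, 5] <- TRUE
  expect_equal(estimate_skeleton_length(one, mpp), 0)
  chain <- matrix(FALSE, 40, 40); chain[10, 11:21] <- TRUE  # 11 px
  expect_equal(estimate_skeleton_length(chain, mpp), 10 * mpp)
  # L-shape: 5 down + 5 across sharing the corner pixel (9 px, 8 steps);
  # the corner's diagonal adjacency is dropped by the triangle rule
  ell <- matrix(FALSE, 40, 40)
  ell[10:14, 10] <- TRUE
  ell[14, 10:14] <- TRUE
  expect_equal(estimate_skeleton_length(ell, mpp), 8 * mpp)
  # pure diagonal chain keeps sqrt(2) steps
  dia <- matrix(FALSE, 40, 40); dia[cbind(1:10, 1:10)] <- TRUE
  expect_equal(estimate_skeleton_length(dia, mpp), 9 * sqrt(2) * mpp)
})

test_that("adding vessel pixels never decreases skeleton length", {
  set.seed(7)
  base <- matrix(FALSE, 80, 80)
  base[40, 10:70] <- TRUE
  l0 <- estimate_skeleton_length(base, 0.01)
  grown <- base
  grown[20, 20:40] <- TRUE
  expect_gte(estimate_skeleton_length(grown, 0.01), l0)
})

test_that("estimated skeleton length is stable under grid refinement", {
  # same physical scene at 1x and 2x resolution
  sc1 <- render_vessel_scene(list(cbind(c(0.3, 2.7), c(1.2, 1.9))),
                             widths_px = 4, grid_px = 245)
  sc2 <- render_vessel_scene(list(cbind(c(0.3, 2.7), c(1.2, 1.9))),
                             widths_px = 8, grid_px = 490)
  l1 <- skeletonize(binarize(sc1$image), 3 / 245)$length_mm
  l2 <- skeletonize(binarize(sc2$image), 3 / 490)$length_mm
  expect_equal(l2, l1, tolerance = 0.03)
})
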