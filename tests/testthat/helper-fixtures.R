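# Shared fixture builders; everything is generated in code at test time.

# A measurement region covering the whole frame (for fractal-dimension
# oracles defined on full images).
full_frame_region <- function(n, mm_per_pixel = 1) {
  m <- matrix(TRUE, n, n)
  attr(m, "mm_per_pixel") <- mm_per_pixel
  suppressWarnings(measurement_region(m, NULL))
}

# Sierpinski carpet of level k as a logical 3^k x 3^k matrix.
sierpinski_carpet <- function(k) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(k)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, m, m), cbind(m, z, m), cbind(m, m, m))
  }
  m
}

# Circle polygon helper (n-gon of given circumradius).
circle_polygon <- function(center, radius, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  faz_polygon(cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)))
}

# Standard 245 px / 3 mm scan geometry.
scan_mpp <- 3 / 245
scan_centre <- (245 - 1) / 2 * scan_mpp

# Enrolment table with disjoint exclusion strata, in flag-precedence order.
make_enrolled <- function(n_fatigue = 15, n_quality = 53, n_disease = 7,
                          n_clean = 90) {
  n <- n_fatigue + n_quality + n_disease + n_clean
  data.frame(
    participant_id = sprintf("E%03d", seq_len(n)),
    fatigue = rep(c(TRUE, FALSE), c(n_fatigue, n - n_fatigue)),
    signal_strength_od = c(rep(9, n_fatigue), rep(5, n_quality),
                           rep(9, n_disease + n_clean)),
    signal_strength_os = c(rep(9, n_fatigue), rep(6, n_quality),
                           rep(9, n_disease + n_clean)),
    eye_disease = rep(c(FALSE, TRUE, FALSE),
                      c(n_fatigue + n_quality, n_disease, n_clean))
  )
}

# Region of measurement for a generated scene (annulus on the FAZ centroid
# minus the FAZ interior).
scene_region <- function(truth) {
  ctr <- faz_center(truth$faz_polygon)
  ann <- annulus_mask(annulus_spec(ctr), dim(truth$image$intensities),
                      truth$image$mm_per_pixel)
  measurement_region(ann, truth$faz_polygon)
}
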