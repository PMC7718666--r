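#' Vessel density within the measurement region
#'
#' Total perfused-vessel centerline length (mm) per unit area (mm^2):
#' the skeleton restricted to the region of measurement, its length by the
#' adjacency-step rule of [estimate_skeleton_length()], divided by the
#' region area.
#'
#' @param skeleton A [skeletonize()] result or logical matrix.
#' @param region A [measurement_region()].
#' @return Vessel density in mm/mm^2.
#' @export
vessel_density <- function(skeleton, region) {
  stopifnot(inherits(region, "measurement_region"))
  s <- as_mask_matrix(skeleton)
  if (!all(dim(s) == dim(region$mask))) {
    stop("skeleton and region shapes differ", call. = FALSE)
  }
  if (region$area_mm2 <= 0) stop("zero-area measurement region", call. = FALSE)
  estimate_skeleton_length(s & region$mask, region$mm_per_pixel) / region$area_mm2
}

#' Perfusion density of large vessels (%)
#'
#' Areal fraction of the measurement region occupied by the large-vessel
#' mask, in percent.
#'
#' @param large_mask A [detect_large_vessels()] result or logical matrix.
#' @param region A [measurement_region()].
#' @return Percentage in `[0, 100]`.
#' @export
large_vessel_perfusion_density <- function(large_mask, region) {
  stopifnot(inherits(region, "measurement_region"))
  m <- as_mask_matrix(large_mask)
  if (!all(dim(m) == dim(region$mask))) {
    stop("mask and region shapes differ", call. = FALSE)
  }
  n_region <- sum(region$mask)
  if (n_region == 0L) stop("zero-area measurement region", call. = FALSE)
  100 * sum(m & region$mask) / n_region
}

#' Box-counting fractal dimension (Dbox)
#'
#' Slope of log N(s) versus log(1/s) over a ladder of box sizes, where N(s)
#' is the number of axis-aligned s x s pixel boxes -- anchored at the
#' region's bounding-box corner -- containing at least one in-region
#' foreground pixel. The default ladder uses powers of two from 2 px up to
#' a quarter of the shorter image side.
#'
#' @param mask Binary vessel mask (any form accepted by [binarize()] output
#'   or a logical matrix).
#' @param region A [measurement_region()] restricting the foreground.
#' @param min_box_px,max_box_px Bounds of the power-of-two box ladder.
#' @return The box-counting dimension (dimensionless).
#' @export
fractal_dimension_boxcount <- function(mask, region, min_box_px = 2L,
                                       max_box_px = NULL) {
  stopifnot(inherits(region, "measurement_region"))
  m <- as_mask_matrix(mask) & region$mask
  if (!any(m)) stop("no in-region foreground for box counting", call. = FALSE)
  if (is.null(max_box_px)) max_box_px <- floor(min(dim(m)) / 4)
  sizes <- 2^(seq.int(floor(log2(min_box_px)), floor(log2(max_box_px))))
  sizes <- sizes[sizes >= min_box_px & sizes <= max_box_px]
  if (length(sizes) < 2L) stop("box ladder needs at least two sizes", call. = FALSE)
  idx <- which(m, arr.ind = TRUE)
  r0 <- min(which(rowSums(region$mask) > 0))
  c0 <- min(which(colSums(region$mask) > 0))
  counts <- vapply(sizes, function(s) {
    bi <- (idx[, 1L] - r0) %/% s
    bj <- (idx[, 2L] - c0) %/% s
    length(unique(bi * (max(bj) + 1L) + bj))
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[[2L]]
}

#' Compute the full per-eye metric record
#'
#' Runs the whole post-processing chain for one eye: binarization and
#' skeletonization of each plexus, FAZ centroid and area, the fovea-centered
#' annulus minus the FAZ interior as region of measurement, vessel density
#' and box-counting fractal dimension per plexus, and large-vessel perfusion
#' density for the SCP. The DCP annulus is centered on the DCP's own FAZ
#' centroid, since the avascular zone differs between plexuses. Missing DCP
#' inputs yield `NA` in the DCP fields.
#'
#' @param scp_image An SCP [en_face_angiogram()].
#' @param dcp_image A DCP [en_face_angiogram()] or `NULL`.
#' @param scp_faz,dcp_faz [faz_polygon()]s delineating each plexus' FAZ
#'   (either may be `NULL`, in which case that annulus is centered on the
#'   image centre and the FAZ is not masked).
#' @param config An [octa_config()] carrying annulus radii, binarization
#'   and large-vessel parameters, the box ladder, and the capillary-only
#'   vessel-density switch.
#' @return A one-row data frame (class `metric_record`) with columns
#'   `participant_id`, `eye`, `vd_scp`, `vd_dcp`, `fd_scp`, `fd_dcp`,
#'   `pd_large_scp`, `faz_area_scp`, `faz_area_dcp`,
#'   `signal_strength_scp`, `signal_strength_dcp`.
#' @export
compute_metric_record <- function(scp_image, dcp_image = NULL,
                                  scp_faz = NULL, dcp_faz = NULL,
                                  config = octa_config()) {
  stopifnot(inherits(scp_image, "en_face_angiogram"))
  scp <- plexus_metrics(scp_image, scp_faz, config, with_large = TRUE)
  if (!is.null(dcp_image)) {
    dcp <- plexus_metrics(dcp_image, dcp_faz, config, with_large = FALSE)
  } else {
    dcp <- list(vd = NA_real_, fd = NA_real_, pd = NA_real_,
                faz_area = NA_real_, signal = NA_real_)
  }
  out <- data.frame(
    participant_id = scp_image$participant_id,
    eye = scp_image$eye,
    vd_scp = scp$vd, vd_dcp = dcp$vd,
    fd_scp = scp$fd, fd_dcp = dcp$fd,
    pd_large_scp = scp$pd,
    faz_area_scp = scp$faz_area, faz_area_dcp = dcp$faz_area,
    signal_strength_scp = scp$signal, signal_strength_dcp = dcp$signal,
    stringsAsFactors = FALSE
  )
  class(out) <- c("metric_record", class(out))
  out
}

plexus_metrics <- function(image, faz, config, with_large) {
  mpp <- image$mm_per_pixel
  dims <- dim(image$intensities)
  bm <- binarize(image, window_px = config$binarize_window_px,
                 offset = config$binarize_offset,
                 min_object_px = config$binarize_min_object_px)
  centre <- if (!is.null(faz)) faz_center(faz) else (dims[c(2L, 1L)] - 1) / 2 * mpp
  spec <- annulus_spec(centre, config$inner_radius_mm, config$outer_radius_mm)
  ann <- annulus_mask(spec, dims, mpp)
  region <- if (is.null(faz)) {
    suppressWarnings(measurement_region(ann, NULL))
  } else {
    measurement_region(ann, faz)
  }
  large <- NULL
  pd <- NA_real_
  vd_mask <- bm$mask
  if (with_large) {
    large <- detect_large_vessels(image,
                                  scales_px = config$large_vessel_scales_px,
                                  vesselness_threshold = config$large_vessel_threshold,
                                  width_floor_px = config$large_vessel_width_floor_px,
                                  mask = bm)
    pd <- large_vessel_perfusion_density(large, region)
    if (config$capillary_only_vd) vd_mask <- vd_mask & !large$mask
  }
  sk <- skeletonize(vd_mask, mm_per_pixel = mpp)
  vd <- vessel_density(sk, region)
  fd <- fractal_dimension_boxcount(bm$mask, region,
                                   min_box_px = config$fd_min_box_px,
                                   max_box_px = config$fd_max_box_px)
  list(vd = vd, fd = fd, pd = pd,
       faz_area = if (!is.null(faz)) faz_area(faz) else NA_real_,
       signal = image$signal_strength)
}
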