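#' Binarize an angiogram or vesselness map
#'
#' Contrast-normalizes the input to the unit interval, then marks a pixel as
#' vessel if it exceeds its local window mean by an offset, or exceeds the
#' global Otsu threshold (which recovers the interior of structures wider
#' than the window). Connected components smaller than `min_object_px` are
#' removed as speckle. The decision depends only on intensity order and
#' contrast, so rescaling the raw intensities leaves the mask unchanged.
#'
#' @param x An [en_face_angiogram()], `vesselness_map`, or numeric matrix.
#' @param window_px Side of the square local-mean window (odd; default 11).
#' @param offset Threshold offset above the local mean on the normalized
#'   scale; `"auto"` (default) uses three times a robust noise-SD estimate,
#'   floored at 0.04, so speckle survives at roughly the 3-sigma rate before
#'   the small-object filter.
#' @param min_object_px Minimum connected-component size kept (8-connectivity).
#' @return A list of class `binary_vessel_mask` with `mask` (logical matrix),
#'   `provenance`, and the `mm_per_pixel` of the source when known.
#' @export
binarize <- function(x, window_px = 11L, offset = "auto", min_object_px = 5L) {
  m <- as_intensity_matrix(x)
  if (any(!is.finite(m))) stop("input contains non-finite values", call. = FALSE)
  mpp <- if (inherits(x, "en_face_angiogram")) x$mm_per_pixel else NA_real_
  rng <- range(m)
  if (diff(rng) < 1e-12) {
    return(new_binary_mask(matrix(FALSE, nrow(m), ncol(m)), "binarize", mpp))
  }
  nm <- (m - rng[1L]) / diff(rng)
  if (identical(offset, "auto")) {
    offset <- max(0.04, 3 * estimate_noise_sd(nm))
  }
  lm <- local_mean(nm, window_px)
  thr_global <- EBImage::otsu(nm, range = c(0, 1))
  mask <- (nm > lm + offset) | (nm > thr_global)
  mask <- remove_small_objects(mask, min_object_px)
  new_binary_mask(mask, "binarize", mpp)
}

#' Detect large vessels in a superficial-plexus angiogram
#'
#' Large (non-capillary) vessels are identified from the binarized plexus by
#' requiring, at a core pixel, both a strong tubularity response at
#' large-vessel scales and a local half-width of at least
#' `width_floor_px / 2` by Euclidean distance transform; cores are then
#' grown back to the full vessel width within the binary mask. Capillary
#' structures (1-2 px) fail the width floor and, being blob-like at these
#' scales where they cross, are also suppressed by the vesselness term.
#' Large-vessel analysis is defined for the SCP only; a DCP image is an
#' error.
#'
#' @param image An [en_face_angiogram()] with `plexus == "SCP"`.
#' @param scales_px Vesselness scales targeting large vessels.
#' @param vesselness_threshold Threshold on the max-normalized vesselness.
#' @param width_floor_px Minimum vessel width (pixels) to count as large;
#'   3 px is about 37 um at the 3 mm / 245 px pitch.
#' @param mask Optional precomputed [binarize()] result for the same image.
#' @return A `binary_vessel_mask` with provenance `"large_vessel"`.
#' @export
detect_large_vessels <- function(image, scales_px = c(2, 3, 4),
                                 vesselness_threshold = 0.25,
                                 width_floor_px = 3, mask = NULL) {
  if (inherits(image, "en_face_angiogram") && image$plexus != "SCP") {
    stop("large-vessel detection is defined for SCP images only", call. = FALSE)
  }
  bm <- if (is.null(mask)) binarize(image) else mask
  m <- bm$mask
  mpp <- if (inherits(image, "en_face_angiogram")) image$mm_per_pixel else NA_real_
  if (!any(m)) return(new_binary_mask(m, "large_vessel", mpp))
  v <- hessian_vesselness(image, scales_px)$responses
  if (max(v) > 0) v <- v / max(v)
  D <- EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m)))
  core <- m & (v > vesselness_threshold) & (D >= width_floor_px / 2)
  core <- remove_small_objects(core, 5L)
  if (!any(core)) return(new_binary_mask(core, "large_vessel", mpp))
  brush <- EBImage::makeBrush(2L * ceiling(width_floor_px) + 1L, shape = "disc")
  grown <- EBImage::dilate(matrix(as.numeric(core), nrow(m), ncol(m)), brush) > 0
  new_binary_mask(m & grown, "large_vessel", mpp)
}

new_binary_mask <- function(mask, provenance, mm_per_pixel = NA_real_) {
  structure(list(mask = mask, provenance = provenance,
                 mm_per_pixel = mm_per_pixel),
            class = "binary_vessel_mask")
}

as_mask_matrix <- function(x) {
  if (inherits(x, "binary_vessel_mask")) return(x$mask)
  if (inherits(x, "skeleton_map")) return(x$skeleton)
  if (is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1)))) {
    return(x > 0)
  }
  stop("expected a binary mask (logical matrix, binary_vessel_mask, or skeleton_map)",
       call. = FALSE)
}

# Box local mean via integral image with edge-corrected counts.
local_mean <- function(m, window_px) {
  r <- (as.integer(window_px) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  Ii <- rbind(0, apply(m, 2L, cumsum))
  Ii <- cbind(0, t(apply(Ii, 1L, cumsum)))
  r2 <- pmin(seq_len(h) + r, h); r1 <- pmax(seq_len(h) - r, 1L) - 1L
  c2 <- pmin(seq_len(w) + r, w); c1 <- pmax(seq_len(w) - r, 1L) - 1L
  S <- Ii[r2 + 1L, c2 + 1L] - Ii[r1 + 1L, c2 + 1L] -
       Ii[r2 + 1L, c1 + 1L] + Ii[r1 + 1L, c1 + 1L]
  counts <- outer(r2 - r1, c2 - c1)
  S / counts
}

# Immerkaer-style robust noise estimate: the 3x3 kernel
# [1,-2,1; -2,4,-2; 1,-2,1] annihilates locally planar structure; for iid
# Gaussian noise its response has SD 6*sigma, and the median absolute
# response of a centred Gaussian is 0.6745 of its SD.
estimate_noise_sd <- function(m) {
  orth <- shift_clamp(m, 0, 1) + shift_clamp(m, 0, -1) +
          shift_clamp(m, 1, 0) + shift_clamp(m, -1, 0)
  diag <- shift_clamp(m, 1, 1) + shift_clamp(m, 1, -1) +
          shift_clamp(m, -1, 1) + shift_clamp(m, -1, -1)
  r <- 4 * m - 2 * orth + diag
  stats::median(abs(r)) / (6 * 0.6745)
}

remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_px)
  if (length(small)) mask[lab %in% small] <- FALSE
  mask
}
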