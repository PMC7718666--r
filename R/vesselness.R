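#' Separable Gaussian smoothing with replicated borders
#'
#' @param m Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; 0 returns `m`.
#' @return Smoothed matrix of the same dimension.
#' @keywords internal
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  R <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-R:R)^2) / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  # rows
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    d <- i - R - 1L
    ri <- pmin(pmax(seq_len(h) + d, 1L), h)
    out <- out + k[i] * m[ri, , drop = FALSE]
  }
  m <- out
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    d <- i - R - 1L
    ci <- pmin(pmax(seq_len(w) + d, 1L), w)
    out <- out + k[i] * m[, ci, drop = FALSE]
  }
  out
}

#' Multi-scale Hessian vesselness (tubularity) filter
#'
#' Eigenvalue-based enhancement of bright tubular structures: at each scale
#' the image is Gaussian-smoothed, the Hessian eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2|} are computed with gamma = 2 scale
#' normalization, and the response combines a blobness term
#' \eqn{\exp(-R_b^2 / 2\beta^2)} with \eqn{R_b = \lambda_1/\lambda_2} and a
#' structureness term \eqn{1 - \exp(-S^2/2c^2)}; only \eqn{\lambda_2 < 0}
#' (bright-on-dark) pixels respond. The final map is the maximum over
#' scales, with the winning scale recorded per pixel.
#'
#' @param image An [en_face_angiogram()] or numeric matrix.
#' @param scales_px Positive Gaussian scales in pixels; the defaults target
#'   vessels of roughly 2.5 px diameter and above at the 3 mm / 245 px pitch.
#' @param beta Blobness sensitivity (default 0.5).
#' @param c_norm Structureness sensitivity; `NULL` uses half the maximum
#'   Hessian norm at each scale.
#' @return A list of class `vesselness_map` with `responses` (non-negative
#'   matrix) and `scales_px` (per-pixel argmax scale; 0 where no response).
#' @export
hessian_vesselness <- function(image, scales_px = c(2, 3, 4), beta = 0.5,
                               c_norm = NULL) {
  if (length(scales_px) < 1L) stop("at least one scale is required", call. = FALSE)
  if (any(scales_px <= 0)) stop("scales must be positive", call. = FALSE)
  m <- as_intensity_matrix(image)
  h <- nrow(m); w <- ncol(m)
  best <- matrix(0, h, w)
  best_scale <- matrix(0, h, w)
  for (s in scales_px) {
    sm <- gaussian_smooth(m, s)
    # second derivatives by central differences on the smoothed image,
    # gamma = 2 normalization (multiply by s^2)
    Ixx <- (shift_clamp(sm, 0, 1) - 2 * sm + shift_clamp(sm, 0, -1)) * s^2
    Iyy <- (shift_clamp(sm, 1, 0) - 2 * sm + shift_clamp(sm, -1, 0)) * s^2
    Ixy <- (shift_clamp(sm, 1, 1) - shift_clamp(sm, 1, -1) -
            shift_clamp(sm, -1, 1) + shift_clamp(sm, -1, -1)) / 4 * s^2
    tr2 <- (Ixx + Iyy) / 2
    disc <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
    la <- tr2 + disc
    lb <- tr2 - disc
    swap <- abs(la) > abs(lb)
    l1 <- ifelse(swap, lb, la)   # smaller magnitude
    l2 <- ifelse(swap, la, lb)   # larger magnitude
    S2 <- l1^2 + l2^2
    cc <- if (is.null(c_norm)) sqrt(max(S2)) / 2 else c_norm
    v <- matrix(0, h, w)
    tube <- l2 < 0
    if (any(tube) && cc > 0) {
      Rb2 <- (l1[tube] / l2[tube])^2
      v[tube] <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2[tube] / (2 * cc^2)))
    }
    better <- v > best
    best[better] <- v[better]
    best_scale[better] <- s
  }
  structure(list(responses = best, scales_px = best_scale, scales = scales_px),
            class = "vesselness_map")
}
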