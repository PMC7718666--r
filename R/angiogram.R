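#' En face OCTA angiogram
#'
#' Container for one plexus' en face angiographic intensity grid together
#' with its physical scale and scan metadata. The coordinate frame places the
#' origin at the centre of the top-left pixel, with x increasing along
#' columns (rightward) and y along rows (downward), both in millimetres; a
#' pixel is an `mm_per_pixel` x `mm_per_pixel` square.
#'
#' @param intensities Numeric H x W matrix of non-negative angiographic
#'   intensities. H and W must both be at least 32.
#' @param mm_per_pixel Physical pixel pitch in mm. The default corresponds to
#'   a 3 x 3 mm scan sampled on a 245 x 245 grid.
#' @param plexus `"SCP"` (superficial) or `"DCP"` (deep capillary plexus).
#' @param signal_strength Device-reported scan quality on a 0-10 scale.
#' @param participant_id,eye Optional identifiers carried through to metric
#'   records.
#' @return An object of class `en_face_angiogram`.
#' @export
en_face_angiogram <- function(intensities,
                              mm_per_pixel = 3 / 245,
                              plexus = c("SCP", "DCP"),
                              signal_strength = 10,
                              participant_id = NA_character_,
                              eye = NA_character_) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("'intensities' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(intensities) < 32L || ncol(intensities) < 32L) {
    stop("angiogram grid must be at least 32 x 32 pixels", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("'intensities' must be finite and non-negative", call. = FALSE)
  }
  stop_if_not_scalar_number(mm_per_pixel, "mm_per_pixel", lower = 1e-9)
  plexus <- match.arg(plexus)
  stop_if_not_scalar_number(signal_strength, "signal_strength", 0, 10)
  structure(
    list(intensities = intensities,
         mm_per_pixel = mm_per_pixel,
         plexus = plexus,
         signal_strength = signal_strength,
         participant_id = as.character(participant_id),
         eye = as.character(eye)),
    class = "en_face_angiogram"
  )
}

#' @export
print.en_face_angiogram <- function(x, ...) {
  cat(sprintf("<en_face_angiogram> %s, %d x %d px, %.4f mm/px, signal %.1f\n",
              x$plexus, nrow(x$intensities), ncol(x$intensities),
              x$mm_per_pixel, x$signal_strength))
  invisible(x)
}

#' Foveal avascular zone boundary polygon
#'
#' An ordered vertex list in the angiogram's physical frame (mm). The polygon
#' must be simple (non-self-intersecting) with at least 3 vertices and
#' positive area; vertex order (clockwise or counter-clockwise) is
#' immaterial, areas are reported as absolute values.
#'
#' @param vertices Two-column numeric matrix or data frame of (x_mm, y_mm)
#'   vertices in order around the boundary.
#' @return An object of class `faz_polygon` (an n x 2 matrix).
#' @export
faz_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || !is.numeric(v)) {
    stop("FAZ polygon needs a two-column numeric vertex matrix", call. = FALSE)
  }
  if (any(!is.finite(v))) stop("FAZ polygon vertices must be finite", call. = FALSE)
  # drop a repeated closing vertex if present
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) stop("FAZ polygon needs at least 3 vertices", call. = FALSE)
  if (polygon_area_signed(v[, 1L], v[, 2L]) == 0) {
    stop("degenerate FAZ polygon: zero area", call. = FALSE)
  }
  if (polygon_self_intersects(v)) {
    stop("FAZ polygon is self-intersecting", call. = FALSE)
  }
  colnames(v) <- c("x_mm", "y_mm")
  structure(v, class = c("faz_polygon", "matrix"))
}

# Signed shoelace area (positive for counter-clockwise in a y-down frame is
# negative; callers take abs() where orientation is immaterial).
polygon_area_signed <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# O(n^2) segment-pair crossing test; polygons here have tens of vertices.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Vectorized even-odd (ray casting) point-in-polygon test.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
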