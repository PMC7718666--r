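#' Fovea-centered measurement annulus
#'
#' The region of measurement is an annulus centered on the FAZ centroid with
#' an inner diameter of 1 mm and an outer diameter of 2.5 mm (radii 0.5 and
#' 1.25 mm).
#'
#' @param center Numeric length-2 `(x_mm, y_mm)` annulus centre.
#' @param inner_radius_mm,outer_radius_mm Annulus radii in mm.
#' @return A list of class `annulus_spec`.
#' @export
annulus_spec <- function(center, inner_radius_mm = 0.5, outer_radius_mm = 1.25) {
  if (length(center) != 2L || any(!is.finite(center))) {
    stop("'center' must be a finite (x_mm, y_mm) pair", call. = FALSE)
  }
  stop_if_not_scalar_number(inner_radius_mm, "inner_radius_mm", lower = 1e-9)
  stop_if_not_scalar_number(outer_radius_mm, "outer_radius_mm", lower = 1e-9)
  if (inner_radius_mm >= outer_radius_mm) {
    stop("inner radius must be smaller than outer radius", call. = FALSE)
  }
  structure(list(center = as.numeric(center),
                 inner_radius_mm = inner_radius_mm,
                 outer_radius_mm = outer_radius_mm),
            class = "annulus_spec")
}

#' Rasterize an annulus onto the image grid
#'
#' A pixel belongs to the annulus iff its centre lies at a distance in
#' `[inner_radius, outer_radius)` from the annulus centre (half-open, so
#' boundary pixels are never double-counted between adjacent rings).
#'
#' @param spec An [annulus_spec()].
#' @param grid_shape Integer `(rows, cols)` of the target grid.
#' @param mm_per_pixel Physical pixel pitch in mm.
#' @return Logical matrix with attributes `mm_per_pixel` and `spec`.
#' @export
annulus_mask <- function(spec, grid_shape, mm_per_pixel) {
  stopifnot(inherits(spec, "annulus_spec"))
  h <- grid_shape[1L]; w <- grid_shape[2L]
  xmax <- (w - 1) * mm_per_pixel; ymax <- (h - 1) * mm_per_pixel
  r <- spec$outer_radius_mm
  tol <- mm_per_pixel / 2
  if (spec$center[1L] - r < -tol || spec$center[1L] + r > xmax + tol ||
      spec$center[2L] - r < -tol || spec$center[2L] + r > ymax + tol) {
    stop("annulus does not fit inside the image field", call. = FALSE)
  }
  xs <- (seq_len(w) - 1) * mm_per_pixel - spec$center[1L]
  ys <- (seq_len(h) - 1) * mm_per_pixel - spec$center[2L]
  d2 <- outer(ys^2, xs^2, `+`)
  m <- d2 >= spec$inner_radius_mm^2 & d2 < spec$outer_radius_mm^2
  attr(m, "mm_per_pixel") <- mm_per_pixel
  attr(m, "spec") <- spec
  m
}

#' Area centroid of a FAZ polygon
#'
#' @param polygon A [faz_polygon()].
#' @return Numeric `(x_mm, y_mm)` centroid of the enclosed area.
#' @export
faz_center <- function(polygon) {
  v <- unclass(polygon)
  if (!is.matrix(v) || ncol(v) != 2L) stop("expected a faz_polygon", call. = FALSE)
  x <- v[, 1L]; y <- v[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("degenerate polygon: zero area", call. = FALSE)
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Area of a FAZ polygon
#'
#' Absolute shoelace area, independent of vertex orientation.
#'
#' @param polygon A [faz_polygon()].
#' @return Area in mm^2.
#' @export
faz_area <- function(polygon) {
  v <- unclass(polygon)
  if (!is.matrix(v) || ncol(v) != 2L) stop("expected a faz_polygon", call. = FALSE)
  a <- abs(polygon_area_signed(v[, 1L], v[, 2L]))
  if (a < 1e-12) stop("degenerate polygon: zero area", call. = FALSE)
  a
}

#' Region of measurement: annulus minus the FAZ interior
#'
#' Masks the manually delineated FAZ out of the annulus so that eyes with a
#' larger avascular zone are not penalized by definitionally vessel-free
#' area. With no polygon the region is the full annulus (with a warning,
#' since unmasked FAZ biases density metrics downward).
#'
#' @param annulus An [annulus_mask()] result.
#' @param polygon A [faz_polygon()] or `NULL`.
#' @return A list of class `measurement_region` with `mask`, `area_mm2`, and
#'   `mm_per_pixel`.
#' @export
measurement_region <- function(annulus, polygon = NULL) {
  mpp <- attr(annulus, "mm_per_pixel")
  if (is.null(mpp)) stop("annulus mask lacks its mm_per_pixel attribute", call. = FALSE)
  m <- annulus
  if (is.null(polygon)) {
    warning("no FAZ polygon supplied; region equals the full annulus")
  } else {
    inside <- faz_interior_mask(polygon, nrow(m), mpp)
    m <- m & !inside
  }
  attr(m, "spec") <- NULL
  if (!any(m)) stop("measurement region is empty", call. = FALSE)
  structure(list(mask = m, area_mm2 = sum(m) * mpp^2, mm_per_pixel = mpp),
            class = "measurement_region")
}
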