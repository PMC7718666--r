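#' Parameters for a synthetic en face angiogram scene
#'
#' Describes one plexus' synthetic vasculature: a handful of large vessels
#' rendered as smooth random-walk polylines of constant width, a jittered
#' capillary mesh of short 1-2 px segments, a central foveal avascular zone
#' kept free of vessels, Gaussian blur at half-pixel scale, and additive
#' Gaussian speckle noise. SCP scenes carry large vessels; DCP scenes default
#' to a mesh-only plexus with a larger FAZ.
#'
#' @param field_mm Physical side length of the scan field (mm).
#' @param grid_px Raster side length in pixels (>= 32).
#' @param n_large_vessels Number of large vessels (0 for DCP-style scenes).
#' @param large_width_um Length-2 range of large-vessel diameters in microns.
#' @param capillary_density Target capillary skeleton length per unit area
#'   (mm/mm^2) over the perfused field. The default keeps the rendered mesh
#'   resolvable at the 245-px sampling of a 3-mm field; anatomical capillary
#'   spacing is finer than this raster can represent.
#' @param faz_area_mm2 Target FAZ area (mm^2); defaults 0.31 for SCP and
#'   1.11 for DCP.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   0-1 intensity scale. Scan signal strength metadata is derived from it
#'   monotonically (10 at zero noise).
#' @param plexus `"SCP"` or `"DCP"`.
#' @param seed Integer seed; identical seeds give bitwise-identical scenes.
#' @return A list of class `angio_scene_params`.
#' @export
angio_scene_params <- function(field_mm = 3,
                               grid_px = 245,
                               n_large_vessels = if (plexus == "SCP") 4L else 0L,
                               large_width_um = c(30, 80),
                               capillary_density = 12,
                               faz_area_mm2 = if (plexus == "SCP") 0.31 else 1.11,
                               noise_sd = 0.05,
                               plexus = c("SCP", "DCP"),
                               seed = 1L) {
  plexus <- match.arg(plexus)
  stop_if_not_scalar_number(field_mm, "field_mm", lower = 1e-6)
  stop_if_not_scalar_number(grid_px, "grid_px", lower = 32)
  stop_if_not_scalar_number(n_large_vessels, "n_large_vessels", lower = 0)
  if (length(large_width_um) != 2L || any(large_width_um <= 0) ||
      large_width_um[2L] < large_width_um[1L]) {
    stop("'large_width_um' must be an increasing positive range", call. = FALSE)
  }
  stop_if_not_scalar_number(capillary_density, "capillary_density", lower = 0)
  stop_if_not_scalar_number(faz_area_mm2, "faz_area_mm2", lower = 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", lower = 0)
  stop_if_not_scalar_number(seed, "seed")
  structure(
    list(field_mm = field_mm, grid_px = as.integer(grid_px),
         n_large_vessels = as.integer(n_large_vessels),
         large_width_um = as.numeric(large_width_um),
         capillary_density = capillary_density,
         faz_area_mm2 = faz_area_mm2, noise_sd = noise_sd,
         plexus = plexus, seed = as.integer(seed)),
    class = "angio_scene_params"
  )
}

#' Generate a synthetic angiogram with exhaustive ground truth
#'
#' Builds the scene described by `params`: a FAZ boundary polygon scaled to
#' the requested area, large-vessel random-walk polylines that are deflected
#' around the FAZ, a jittered square mesh of capillary segments thinned to
#' the target length density, and the rendered intensity image (bright
#' vessels on a dark background, half-pixel Gaussian blur, additive noise).
#'
#' @param params An [angio_scene_params()] object.
#' @return A list of class `angiogram_truth` with elements `image`
#'   (an [en_face_angiogram()]), `vessel_mask`, `large_vessel_mask`,
#'   `skeleton_mask` (rasterized generating centerlines), `skeleton_length_mm`
#'   (analytic centerline length), `centerlines`, `faz_polygon`, and `params`.
#' @export
generate_vessel_network <- function(params) {
  stopifnot(inherits(params, "angio_scene_params"))
  g <- params$grid_px
  mpp <- params$field_mm / g
  wmax_px <- params$large_width_um[2L] * 1e-3 / mpp
  if (params$n_large_vessels > 0L && wmax_px > g / 8) {
    stop(sprintf("grid of %d px is too small to render %g um vessels", g,
                 params$large_width_um[2L]), call. = FALSE)
  }
  with_seed(params$seed, {
    centre <- rep(params$field_mm / 2, 2)

    ## FAZ boundary: a jittered, rotated ellipse rescaled to the exact area.
    faz <- NULL
    r_excl <- 0
    if (params$faz_area_mm2 > 0) {
      faz_centre <- centre + stats::runif(2, -0.05, 0.05)
      faz <- make_faz_polygon(faz_centre, params$faz_area_mm2)
      r_excl <- max(sqrt((faz[, 1] - faz_centre[1])^2 +
                         (faz[, 2] - faz_centre[2])^2))
    } else {
      faz_centre <- centre
    }

    ## Large vessels: smooth random walks from a field edge, kept clear of
    ## the FAZ by a margin of half their width plus one pixel.
    large <- list()
    if (params$n_large_vessels > 0L) {
      for (k in seq_len(params$n_large_vessels)) {
        w_um <- stats::runif(1, params$large_width_um[1L], params$large_width_um[2L])
        w_px <- w_um * 1e-3 / mpp
        margin <- r_excl + (w_px / 2 + 1) * mpp
        path <- walk_vessel(params$field_mm, faz_centre, margin, step_mm = 2 * mpp)
        large[[k]] <- list(xy = path, width_px = w_px, type = "large")
      }
    }

    ## Capillary mesh: jittered square lattice edges, FAZ-excluded, thinned
    ## to the target total skeleton length. Edges entering the large-vessel
    ## footprint are rejected: a capillary does not run through a larger
    ## vessel's lumen, and centerline length hidden under a wide vessel
    ## would count as ground truth no skeleton could recover.
    large_footprint <- rasterize_tubes(large, g, mpp)
    if (any(large_footprint)) {
      large_footprint <- EBImage::dilate(
        matrix(as.numeric(large_footprint), g, g),
        EBImage::makeBrush(3L, shape = "box")) > 0
    }
    caps <- list()
    if (params$capillary_density > 0) {
      d <- 2 / params$capillary_density
      margin <- r_excl + 1.5 * mpp
      edges <- mesh_edges(params$field_mm, d, faz_centre, margin)
      if (any(large_footprint) && length(edges)) {
        clear <- vapply(edges, function(e) {
          ts <- seq(0, 1, length.out = 7L)
          cx <- floor((e[1, 1] + ts * (e[2, 1] - e[1, 1])) / mpp + 0.5) + 1L
          cy <- floor((e[1, 2] + ts * (e[2, 2] - e[1, 2])) / mpp + 0.5) + 1L
          ok <- cx >= 1L & cx <= g & cy >= 1L & cy <= g
          !any(large_footprint[cbind(cy[ok], cx[ok])])
        }, logical(1))
        edges <- edges[clear]
      }
      if (length(edges)) {
        lens <- vapply(edges, function(e) seg_length(e), numeric(1))
        target <- params$capillary_density *
          (params$field_mm^2 - pi * min(margin, params$field_mm / 2)^2)
        keep <- if (sum(lens) > target) {
          stats::runif(length(edges)) < target / sum(lens)
        } else rep(TRUE, length(edges))
        edges <- edges[keep]
      }
      caps <- lapply(edges, function(e) {
        list(xy = e, width_px = stats::runif(1, 1, 2), type = "capillary")
      })
    }

    vessels <- c(large, caps)
    skeleton_length_mm <- if (length(vessels)) {
      sum(vapply(vessels, function(v) seg_length(v$xy), numeric(1)))
    } else 0

    skeleton_mask <- rasterize_tubes(vessels, g, mpp, centerline_only = TRUE)
    vessel_mask <- rasterize_tubes(vessels, g, mpp)
    large_vessel_mask <- rasterize_tubes(large, g, mpp)

    ## enforce a vessel-free FAZ interior (margins make this a no-op in
    ## practice, but the invariant is guaranteed, not assumed)
    if (!is.null(faz)) {
      inside <- faz_interior_mask(faz, g, mpp)
      vessel_mask[inside] <- FALSE
      large_vessel_mask[inside] <- FALSE
      skeleton_mask[inside] <- FALSE
    }

    img <- matrix(0.2, g, g)
    cap_mask <- vessel_mask & !large_vessel_mask
    img[cap_mask] <- 0.85
    img[large_vessel_mask] <- 0.95
    img <- gaussian_smooth(img, 0.5)
    if (params$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(g * g, 0, params$noise_sd), g, g)
    }
    img <- pmin(pmax(img, 0), 1)

    ss <- round(max(0, min(10, 10 - 40 * params$noise_sd)), 1)
    image <- en_face_angiogram(img, mm_per_pixel = mpp, plexus = params$plexus,
                               signal_strength = ss)
    structure(
      list(image = image, vessel_mask = vessel_mask,
           large_vessel_mask = large_vessel_mask,
           skeleton_mask = skeleton_mask,
           skeleton_length_mm = skeleton_length_mm,
           centerlines = vessels, faz_polygon = faz, params = params),
      class = "angiogram_truth"
    )
  })
}

#' Render a vessel scene from explicit centerlines
#'
#' Low-level renderer used by [generate_vessel_network()] and by validation
#' fixtures that need exactly-known geometry (straight tubes, width sweeps).
#' Draws each polyline at the given width, blurs at half-pixel sigma, and
#' adds Gaussian noise.
#'
#' @param centerlines List of two-column (x_mm, y_mm) matrices.
#' @param widths_px Numeric vector of rendered widths (pixels), recycled.
#' @param field_mm,grid_px Field geometry as in [angio_scene_params()].
#' @param noise_sd Additive noise SD; 0 for noise-free fixtures.
#' @param plexus Plexus label for the returned angiogram.
#' @param intensity Foreground intensity before blurring.
#' @return A list with `image`, `vessel_mask`, `skeleton_mask`, and
#'   `skeleton_length_mm` (analytic).
#' @export
render_vessel_scene <- function(centerlines, widths_px, field_mm = 3,
                                grid_px = 245, noise_sd = 0,
                                plexus = "SCP", intensity = 0.9) {
  g <- as.integer(grid_px)
  mpp <- field_mm / g
  widths_px <- rep_len(widths_px, length(centerlines))
  vessels <- Map(function(xy, w) list(xy = as.matrix(xy), width_px = w),
                 centerlines, widths_px)
  vessel_mask <- rasterize_tubes(vessels, g, mpp)
  skeleton_mask <- rasterize_tubes(vessels, g, mpp, centerline_only = TRUE)
  img <- matrix(0.2, g, g)
  img[vessel_mask] <- intensity
  img <- gaussian_smooth(img, 0.5)
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(g * g, 0, noise_sd), g, g)
  img <- pmin(pmax(img, 0), 1)
  list(image = en_face_angiogram(img, mm_per_pixel = mpp, plexus = plexus),
       vessel_mask = vessel_mask, skeleton_mask = skeleton_mask,
       skeleton_length_mm = sum(vapply(vessels, function(v) seg_length(v$xy),
                                       numeric(1))))
}

#' Analytic centerline length inside a measurement region
#'
#' Integrates the generating centerlines of an [generate_vessel_network()]
#' scene over the pixels of a measurement region, giving the ground-truth
#' in-region skeleton length independent of any rasterization.
#'
#' @param truth An `angiogram_truth` object.
#' @param region A [measurement_region()] on the same grid.
#' @param step_px Sampling step along the centerlines, in pixels.
#' @return Length in mm.
#' @export
scene_region_length <- function(truth, region, step_px = 0.1) {
  stopifnot(inherits(truth, "angiogram_truth"),
            inherits(region, "measurement_region"))
  mpp <- truth$image$mm_per_pixel
  g <- nrow(region$mask)
  total <- 0
  for (v in truth$centerlines) {
    xy <- v$xy
    for (s in seq_len(nrow(xy) - 1L)) {
      a <- xy[s, ]; b <- xy[s + 1L, ]
      len <- sqrt(sum((b - a)^2))
      n <- max(2L, ceiling(len / (step_px * mpp)))
      ts <- (seq_len(n) - 0.5) / n
      cx <- floor((a[1] + ts * (b[1] - a[1])) / mpp + 0.5) + 1L
      cy <- floor((a[2] + ts * (b[2] - a[2])) / mpp + 0.5) + 1L
      inside <- cx >= 1L & cx <= g & cy >= 1L & cy <= g
      inside[inside] <- region$mask[cbind(cy[inside], cx[inside])]
      total <- total + len * sum(inside) / n
    }
  }
  total
}

## ---- internal geometry helpers ------------------------------------------

seg_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

# Jittered ellipse with low-order Fourier boundary perturbation, rescaled so
# the shoelace area matches the target exactly.
make_faz_polygon <- function(centre, area_mm2, n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  aspect <- stats::runif(1, 0.85, 1.2)
  rot <- stats::runif(1, 0, pi)
  ab <- stats::rnorm(4, 0, 0.03)
  r <- 1 + ab[1] * cos(th) + ab[2] * sin(th) + ab[3] * cos(2 * th) + ab[4] * sin(2 * th)
  x0 <- r * aspect * cos(th)
  y0 <- r / aspect * sin(th)
  x <- x0 * cos(rot) - y0 * sin(rot)
  y <- x0 * sin(rot) + y0 * cos(rot)
  a0 <- abs(polygon_area_signed(x, y))
  s <- sqrt(area_mm2 / a0)
  faz_polygon(cbind(centre[1] + s * x, centre[2] + s * y))
}

# Random-walk polyline across the field, entering from a random edge and
# deflected so it never comes within `margin` of the FAZ centre.
walk_vessel <- function(field_mm, faz_centre, margin, step_mm,
                        heading_sd = 0.12) {
  side <- sample.int(4L, 1L)
  t0 <- stats::runif(1, 0.1, 0.9) * field_mm
  start <- switch(side,
                  c(0, t0), c(field_mm, t0), c(t0, 0), c(t0, field_mm))
  heading <- atan2(field_mm / 2 - start[2], field_mm / 2 - start[1]) +
    stats::rnorm(1, 0, 0.3)
  pts <- matrix(NA_real_, ceiling(2 * field_mm / step_mm) + 2L, 2L)
  pts[1L, ] <- start
  pos <- start
  n <- 1L
  max_steps <- nrow(pts) - 1L
  for (i in seq_len(max_steps)) {
    heading <- heading + stats::rnorm(1, 0, heading_sd)
    cand <- pos + step_mm * c(cos(heading), sin(heading))
    tries <- 0L
    while (sqrt(sum((cand - faz_centre)^2)) < margin && tries < 12L) {
      # turn away from the FAZ centre
      away <- atan2(pos[2] - faz_centre[2], pos[1] - faz_centre[1])
      dh <- (away - heading + pi) %% (2 * pi) - pi
      heading <- heading + sign(dh + 1e-9) * 0.35
      cand <- pos + step_mm * c(cos(heading), sin(heading))
      tries <- tries + 1L
    }
    if (any(cand < 0) || any(cand > field_mm)) break
    n <- n + 1L
    pts[n, ] <- cand
    pos <- cand
  }
  pts[seq_len(n), , drop = FALSE]
}

# Edges of a jittered square lattice, clipped to the field and FAZ-excluded.
mesh_edges <- function(field_mm, spacing, faz_centre, margin) {
  ax <- seq(spacing / 2, field_mm - spacing / 2, by = spacing)
  if (length(ax) < 2L) return(list())
  nx <- length(ax)
  nodes_x <- outer(ax, rep(1, nx)) + matrix(stats::runif(nx * nx, -0.3, 0.3) * spacing, nx, nx)
  nodes_y <- outer(rep(1, nx), ax) + matrix(stats::runif(nx * nx, -0.3, 0.3) * spacing, nx, nx)
  edges <- vector("list", 2L * nx * nx)
  m <- 0L
  ok <- function(p) {
    p[1] >= 0 && p[1] <= field_mm && p[2] >= 0 && p[2] <= field_mm &&
      sqrt(sum((p - faz_centre)^2)) >= margin
  }
  for (i in seq_len(nx)) {
    for (j in seq_len(nx)) {
      a <- c(nodes_x[i, j], nodes_y[i, j])
      if (i < nx) {
        b <- c(nodes_x[i + 1L, j], nodes_y[i + 1L, j])
        if (ok(a) && ok(b) && ok((a + b) / 2)) {
          m <- m + 1L; edges[[m]] <- rbind(a, b)
        }
      }
      if (j < nx) {
        b <- c(nodes_x[i, j + 1L], nodes_y[i, j + 1L])
        if (ok(a) && ok(b) && ok((a + b) / 2)) {
          m <- m + 1L; edges[[m]] <- rbind(a, b)
        }
      }
    }
  }
  edges[seq_len(m)]
}

# Stamp polylines onto the raster: each sample point along a centerline
# marks the pixels whose centres lie within half the vessel width.
rasterize_tubes <- function(vessels, grid_px, mpp, centerline_only = FALSE) {
  mask <- matrix(FALSE, grid_px, grid_px)
  if (!length(vessels)) return(mask)
  for (v in vessels) {
    xy <- v$xy
    if (nrow(xy) < 2L) next
    if (centerline_only) {
      # 8-connected chain (Bresenham), so the rasterized centerline has the
      # same diagonal-step structure as a thinned skeleton
      for (s in seq_len(nrow(xy) - 1L)) {
        pts <- bresenham_px(xy[s, ], xy[s + 1L, ], mpp)
        keep <- pts[, 1L] >= 1L & pts[, 1L] <= grid_px &
                pts[, 2L] >= 1L & pts[, 2L] <= grid_px
        mask[pts[keep, , drop = FALSE]] <- TRUE
      }
      next
    }
    r_px <- v$width_px / 2
    R <- floor(r_px + 0.5)
    off <- expand.grid(dr = -R:R, dc = -R:R)
    off <- off[off$dr^2 + off$dc^2 <= max(r_px, 0.5)^2 + 1e-9, , drop = FALSE]
    step <- 0.25  # px between samples along the centerline
    for (s in seq_len(nrow(xy) - 1L)) {
      a <- xy[s, ]; b <- xy[s + 1L, ]
      len_px <- sqrt(sum((b - a)^2)) / mpp
      ts <- seq(0, 1, length.out = max(2L, ceiling(len_px / step) + 1L))
      cx <- floor((a[1] + ts * (b[1] - a[1])) / mpp + 0.5) + 1L
      cy <- floor((a[2] + ts * (b[2] - a[2])) / mpp + 0.5) + 1L
      pts <- unique(cbind(cy, cx))
      rows <- rep(pts[, 1L], each = nrow(off)) + off$dr
      cols <- rep(pts[, 2L], each = nrow(off)) + off$dc
      keep <- rows >= 1L & rows <= grid_px & cols >= 1L & cols <= grid_px
      mask[cbind(rows[keep], cols[keep])] <- TRUE
    }
  }
  mask
}

# Integer pixel chain between two mm-frame points; steps the major axis one
# pixel at a time and rounds the minor axis, giving an 8-connected line.
bresenham_px <- function(a, b, mpp) {
  c0 <- floor(a[1] / mpp + 0.5); r0 <- floor(a[2] / mpp + 0.5)
  c1 <- floor(b[1] / mpp + 0.5); r1 <- floor(b[2] / mpp + 0.5)
  dc <- c1 - c0; dr <- r1 - r0
  n <- max(abs(dc), abs(dr))
  if (n == 0) return(cbind(r0 + 1L, c0 + 1L))
  t <- 0:n
  if (abs(dc) >= abs(dr)) {
    cs <- c0 + t * sign(dc)
    rs <- r0 + floor(t * dr / abs(dc) + 0.5) * 1
  } else {
    rs <- r0 + t * sign(dr)
    cs <- c0 + floor(t * dc / abs(dr) + 0.5) * 1
  }
  cbind(as.integer(rs) + 1L, as.integer(cs) + 1L)
}

# Boolean grid of pixels whose centres fall inside the FAZ polygon.
faz_interior_mask <- function(faz, grid_px, mpp) {
  xs <- (seq_len(grid_px) - 1) * mpp
  bb <- apply(faz, 2L, range)
  ci <- which(xs >= bb[1, 1] - mpp & xs <= bb[2, 1] + mpp)
  ri <- which(xs >= bb[1, 2] - mpp & xs <= bb[2, 2] + mpp)
  inside <- matrix(FALSE, grid_px, grid_px)
  if (!length(ci) || !length(ri)) return(inside)
  px <- rep(xs[ci], each = length(ri))
  py <- rep(xs[ri], times = length(ci))
  hit <- points_in_polygon(px, py, faz)
  inside[cbind(rep(ri, times = length(ci)), rep(ci, each = length(ri)))] <- hit
  inside
}
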