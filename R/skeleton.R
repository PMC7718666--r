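#' Morphological skeletonization (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels in two alternating sub-iterations until
#' stable, yielding a one-pixel-wide, 8-connected medial skeleton that
#' preserves the topology of connected tubes. Skeletonizing a skeleton
#' returns it unchanged.
#'
#' @param mask A [binarize()] result or logical matrix.
#' @param mm_per_pixel Physical pixel pitch used to report the skeleton
#'   length; taken from the mask when available.
#' @return A list of class `skeleton_map` with `skeleton` (logical matrix),
#'   `length_mm` (see [estimate_skeleton_length()]; `NA` when the scale is
#'   unknown), and `mm_per_pixel`.
#' @export
skeletonize <- function(mask, mm_per_pixel = NULL) {
  m <- as_mask_matrix(mask)
  if (is.null(mm_per_pixel)) {
    mm_per_pixel <- if (inherits(mask, "binary_vessel_mask")) mask$mm_per_pixel else NA_real_
  }
  sk <- thin_zhang_suen(m)
  sk <- remove_staircases(sk)
  sk <- extend_endpoints(sk, m)
  len <- if (is.finite(mm_per_pixel)) {
    estimate_skeleton_length(sk, mm_per_pixel)
  } else NA_real_
  structure(list(skeleton = sk, length_mm = len, mm_per_pixel = mm_per_pixel),
            class = "skeleton_map")
}

thin_zhang_suen <- function(m) {
  m <- m * 1L  # integer arithmetic on 0/1
  storage.mode(m) <- "integer"
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours p2..p9 clockwise from north (row-1); x = cols, y = rows
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1L) {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Zhang-Suen leaves staircase corners: pixels whose only two neighbours are
# perpendicular orthogonal pixels. Removing such a corner keeps its two
# neighbours diagonally connected, turning the 4-connected staircase into
# the 8-connected diagonal chain the length rule expects. Applied
# sequentially with re-checks so adjacent corners cannot both vanish.
remove_staircases <- function(sk) {
  h <- nrow(sk); c_n <- ncol(sk)
  orth <- rbind(N = c(-1L, 0L), E = c(0L, 1L), S = c(1L, 0L), W = c(0L, -1L))
  diags <- rbind(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  at <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= c_n && sk[r, c]
  repeat {
    # candidates: pixels with exactly two orthogonal neighbours
    n_orth <- matrix(0L, h, c_n)
    for (k in 1:4) n_orth <- n_orth + shift_mat(sk * 1L, -orth[k, 1L], -orth[k, 2L])
    cand <- which(sk & n_orth == 2L, arr.ind = TRUE)
    removed <- FALSE
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      on_orth <- vapply(1:4, function(k) at(r + orth[k, 1L], c + orth[k, 2L]),
                        logical(1))
      if (sum(on_orth) != 2L ||
          (on_orth[1L] && on_orth[3L]) || (on_orth[2L] && on_orth[4L])) next
      opix <- orth[on_orth, , drop = FALSE]
      opix[, 1L] <- opix[, 1L] + r; opix[, 2L] <- opix[, 2L] + c
      dpix <- diags
      dpix[, 1L] <- dpix[, 1L] + r; dpix[, 2L] <- dpix[, 2L] + c
      ok <- TRUE
      for (k in 1:4) {
        if (at(dpix[k, 1L], dpix[k, 2L])) {
          # every diagonal neighbour must stay connected through an
          # orthogonal neighbour once the corner pixel is gone
          touches <- any(abs(dpix[k, 1L] - opix[, 1L]) <= 1L &
                         abs(dpix[k, 2L] - opix[, 2L]) <= 1L)
          if (!touches) { ok <- FALSE; break }
        }
      }
      if (ok) {
        sk[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

# Thinning retracts the ends of a tube by about half its width; recover the
# lost length by marching each skeleton endpoint along its local direction
# while still inside the source mask. On input that is already a thin
# skeleton the mask offers no room, so the step is a no-op (idempotence).
extend_endpoints <- function(sk, mask, max_steps = 64L) {
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  h <- nrow(sk); w <- ncol(sk)
  deg <- matrix(0L, h, w)
  for (k in seq_len(nrow(nb))) deg <- deg + shift_mat(sk * 1L, nb$dr[k], nb$dc[k])
  ends <- which(sk & deg == 1L, arr.ind = TRUE)
  for (e in seq_len(nrow(ends))) {
    r <- ends[e, 1L]; c <- ends[e, 2L]
    # direction away from the unique neighbour
    nbr <- NULL
    for (k in seq_len(nrow(nb))) {
      rr <- r + nb$dr[k]; cc <- c + nb$dc[k]
      if (rr >= 1L && rr <= h && cc >= 1L && cc <= w && sk[rr, cc]) {
        nbr <- c(nb$dr[k], nb$dc[k]); break
      }
    }
    if (is.null(nbr)) next
    dr <- -nbr[1L]; dc <- -nbr[2L]
    for (s in seq_len(max_steps)) {
      r <- r + dr; c <- c + dc
      if (r < 1L || r > h || c < 1L || c > w || !mask[r, c] || sk[r, c]) break
      sk[r, c] <- TRUE
    }
  }
  sk
}

#' Physical length of a pixel skeleton
#'
#' Sums step lengths over adjacent skeleton-pixel pairs -- 1 pixel for
#' orthogonal neighbours, sqrt(2) for diagonal neighbours -- with each
#' adjacency counted once, scaled by `mm_per_pixel`. Where a diagonal
#' adjacency closes a triangle with an orthogonal path (both pixels share an
#' orthogonal skeleton neighbour), the diagonal is dropped: the orthogonal
#' chain already traverses that span, and counting both would overstate the
#' length.
#'
#' @param skeleton A `skeleton_map` or logical matrix.
#' @param mm_per_pixel Physical pixel pitch in mm.
#' @return Total centerline length in mm (0 for an empty or single-pixel
#'   skeleton).
#' @export
estimate_skeleton_length <- function(skeleton, mm_per_pixel) {
  stop_if_not_scalar_number(mm_per_pixel, "mm_per_pixel", lower = 1e-12)
  s <- as_mask_matrix(skeleton)
  if (!any(s)) return(0)
  right <- s & shift_mat(s, 0, -1) > 0     # (i,j)-(i,j+1)
  down  <- s & shift_mat(s, -1, 0) > 0     # (i,j)-(i+1,j)
  dr    <- s & shift_mat(s, -1, -1) > 0    # (i,j)-(i+1,j+1)
  dl    <- s & shift_mat(s, -1, 1) > 0     # (i,j)-(i+1,j-1)
  # triangle correction: drop a diagonal when either orthogonal corner pixel
  # of its unit square is also skeleton
  dr_keep <- dr & !((shift_mat(s, -1, 0) > 0) | (shift_mat(s, 0, -1) > 0))
  dl_keep <- dl & !((shift_mat(s, -1, 0) > 0) | (shift_mat(s, 0, 1) > 0))
  n_orth <- sum(right) + sum(down)
  n_diag <- sum(dr_keep) + sum(dl_keep)
  (n_orth + sqrt(2) * n_diag) * mm_per_pixel
}
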