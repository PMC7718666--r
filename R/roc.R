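#' ROC area under the curve
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted one half:
#' the probability that a random case scores above a random control, plus
#' half the probability of a tie. The orientation is reported as-is -- an
#' AUC below 0.5 is flagged, not flipped.
#'
#' @param scores Numeric marker values.
#' @param labels Class labels coercible to two levels; the positive class is
#'   `TRUE`, `1`, or the second factor level.
#' @return A list of class `roc_result` with `auc`, `n_pos`, `n_neg`, and
#'   `below_chance`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores/labels length mismatch", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(auc = auc, n_pos = n1, n_neg = n0,
                 below_chance = auc < 0.5),
            class = "roc_result")
}

#' ROC curve vertices
#'
#' Vertices of the empirical ROC polyline, from (0, 0) through one vertex
#' per distinct threshold to (1, 1), as (false positive rate, sensitivity)
#' pairs.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n0, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Sensitivity at a fixed specificity
#'
#' Reads the ROC polyline at the requested specificity, interpolating
#' linearly between adjacent vertices (at a vertical segment the upper
#' vertex is used). An uninformative, all-ties marker therefore returns
#' `1 - specificity`, the chance diagonal.
#'
#' @inheritParams roc_auc
#' @param specificity Target specificity in (0, 1); the default operating
#'   point is 0.415.
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at_specificity <- function(scores, labels, specificity = 0.415) {
  stop_if_not_scalar_number(specificity, "specificity", lower = 0, upper = 1)
  rc <- roc_curve(scores, labels)
  target_fpr <- 1 - specificity
  fpr <- c(rc$fpr, 1); tpr <- c(rc$tpr, 1)
  stats::approx(fpr, tpr, xout = target_fpr, ties = max)$y
}

#' Paired comparison of two correlated AUCs (DeLong)
#'
#' Tests the difference of two markers' AUCs measured on the same subjects
#' using the structural-components estimate of the covariance between
#' correlated AUCs, with a two-sided normal reference. Comparing a marker
#' with itself (zero-variance difference) reports a difference of 0 with
#' p = 1 by convention.
#'
#' @param marker_a,marker_b Numeric scores on the same subjects.
#' @param labels Class labels (see [roc_auc()]).
#' @return A list with `auc_a`, `auc_b`, `difference`, `z`, and `p_value`.
#' @export
compare_auc_paired <- function(marker_a, marker_b, labels) {
  y <- as_binary_labels(labels)
  if (length(marker_a) != length(y) || length(marker_b) != length(y)) {
    stop("markers and labels must have equal length", call. = FALSE)
  }
  pos <- y == 1L; neg <- y == 0L
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  comp <- function(s) {
    # psi(x_i, y_j) = 1, 1/2, 0 for case > / = / < control
    psi <- outer(s[pos], s[neg],
                 function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  a <- comp(marker_a); b <- comp(marker_b)
  d <- a$auc - b$auc
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (var_d < 1e-16) {
    return(list(auc_a = a$auc, auc_b = b$auc, difference = 0, z = 0, p_value = 1))
  }
  z <- d / sqrt(var_d)
  list(auc_a = a$auc, auc_b = b$auc, difference = d, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    l <- droplevels(labels)
    if (nlevels(l) > 2L) stop("labels must be binary", call. = FALSE)
    return(as.integer(l == levels(l)[nlevels(l)]))
  }
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("labels must be binary", call. = FALSE)
  if (length(u) == 1L) return(as.integer(labels == u))  # single class; caught later
  as.integer(labels == u[2L])
}
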