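# Contour and annulus primitives: orientation, equidistant resampling,
# boundary pairing, annulus membership.
#
# Coordinate convention (used package-wide): image coordinates with
# x = column and y = row; pixel (row r, col c) has its centre at the
# continuous position (x = c, y = r), 1-based. "Counter-clockwise" means
# shoelace signed area > 0 in this frame (see `signed_area()`), which is
# the direction of increasing azimuth atan2(y - oy, x - ox).

#' Normalize a boundary contour
#'
#' Brings a raw closed contour into the canonical form used throughout the
#' pipeline: consecutive duplicate vertices removed, orientation
#' counter-clockwise (positive signed area), resampled to exactly
#' `n_points` equidistant points, with the start point preserved as the
#' resampled point nearest the original first vertex. Resampling is
#' piecewise linear and iterated to its equal-chord fixed point, so the
#' output's consecutive spacing is uniform and renormalizing an already
#' normalized contour leaves it unchanged (to 1e-9); periodic cubic
#' splines are fitted later where a smooth curve is needed.
#'
#' @param raw n x 2 matrix of (x, y) vertices of a simple closed polygon.
#' @param n_points number of output points (>= 3).
#' @return `n_points` x 2 matrix, counter-clockwise, equidistant.
#' @export
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' normalize_contour(sq, 8)
normalize_contour <- function(raw, n_points) {
  raw <- dedupe_vertices(as_xy(raw))
  if (n_points < 3L)
    cyclo_stop("n_points must be >= 3", "cyclo_parameter_error")
  if (nrow(raw) < 3L)
    cyclo_stop("contour needs at least 3 distinct points",
               "cyclo_invalid_contour")
  if (contour_perimeter(raw) <= 0)
    cyclo_stop("zero-perimeter contour", "cyclo_invalid_contour")
  first <- raw[1L, ]
  if (signed_area(raw) < 0)
    raw <- raw[rev(seq_len(nrow(raw))), , drop = FALSE]
  out <- resample_equal_chords(raw, n_points, closed = TRUE)
  k <- which.min((out[, 1L] - first[1L])^2 + (out[, 2L] - first[2L])^2)
  rotate_start(out, k)
}

## even-odd point-in-polygon via pracma; pts is n x 2
point_in_polygon <- function(pts, poly, boundary = FALSE) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  pts <- as_xy(pts)
  pracma::inpolygon(pts[, 1L], pts[, 2L], poly[, 1L], poly[, 2L],
                    boundary = boundary)
}

#' Pair inner and outer boundary contours into an annulus section
#'
#' The outer contour is cyclically re-indexed so that its first point is
#' the one nearest (Euclidean) to the inner contour's first point; this
#' keeps point indices on the two boundaries roughly radially aligned,
#' which the later surface construction and mapping rely on. Coordinates
#' are never changed, only the cyclic start index of the outer contour.
#'
#' @param inner,outer contours normalized to the same point count
#'   (see [normalize_contour()]), inner strictly inside outer.
#' @param slice 1-based slice index this section belongs to (optional).
#' @return An object of class `annulus_section`: list with elements
#'   `inner`, `outer` (I x 2 matrices) and `slice`.
#' @export
pair_boundaries <- function(inner, outer, slice = NA_integer_) {
  inner <- as_xy(inner); outer <- as_xy(outer)
  if (nrow(inner) != nrow(outer))
    cyclo_stop("inner and outer contours must have the same point count",
               "cyclo_contract_error")
  if (signed_area(inner) <= 0 || signed_area(outer) <= 0)
    cyclo_stop("contours must be counter-clockwise; run normalize_contour()",
               "cyclo_contract_error")
  if (!all(point_in_polygon(inner, outer, boundary = FALSE)))
    cyclo_stop("inner contour is not strictly inside the outer contour",
               "cyclo_geometry_error")
  d2 <- (outer[, 1L] - inner[1L, 1L])^2 + (outer[, 2L] - inner[1L, 2L])^2
  structure(
    list(inner = inner, outer = rotate_start(outer, which.min(d2)),
         slice = as.integer(slice)),
    class = "annulus_section"
  )
}

#' @export
print.annulus_section <- function(x, ...) {
  cat(sprintf(
    "annulus section (slice %s): %d boundary points, perimeters %.1f / %.1f px\n",
    ifelse(is.na(x$slice), "?", x$slice), nrow(x$inner),
    contour_perimeter(x$inner), contour_perimeter(x$outer)))
  invisible(x)
}

#' Annulus membership test
#'
#' A point belongs to the annulus iff it is strictly inside the outer
#' polygon and strictly outside the inner polygon (even-odd rule). Points
#' exactly on either boundary are NOT in the annulus, so a field line
#' stepping onto the outer boundary terminates cleanly.
#'
#' @param pts n x 2 matrix (or length-2 vector) of positions.
#' @param section an `annulus_section`.
#' @return Logical vector of length n.
#' @export
annulus_contains <- function(pts, section) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  point_in_polygon(pts, section$outer, boundary = FALSE) &
    !point_in_polygon(pts, section$inner, boundary = TRUE)
}
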