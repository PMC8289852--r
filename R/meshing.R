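# From complete field lines to internal contours at C relative depth
# levels on key slices, and vertical interpolation across all slices into
# a set of nested onion-like re-slicing surfaces.

#' Relative depth levels
#'
#' The C relative depth levels `c/(C-1) * 100%` for `c = 0 .. C-1`;
#' level 0% is the inner boundary and 100% the outer boundary. For C = 3
#' the levels are 0%, 50%, 100%; for C = 4 they are 0%, 33 1/3%, 66 2/3%,
#' 100%.
#'
#' @param n_levels C, number of depth levels (>= 2).
#' @return Numeric vector of percentages, length `n_levels`.
#' @export
depth_levels <- function(n_levels) {
  if (n_levels < 2L)
    cyclo_stop("need at least 2 depth levels", "cyclo_parameter_error")
  (0:(n_levels - 1L)) / (n_levels - 1L) * 100
}

#' Key slice indices
#'
#' Field lines are traced only on every `m`-th slice (the interpolation
#' interval); slices in between get their contours from vertical cubic
#' splines. The last slice is always a key slice so the vertical splines
#' never extrapolate.
#'
#' @param n_slices H, total number of slices.
#' @param m interpolation interval in slices (positive integer).
#' @return Sorted integer vector of 1-based key slice indices.
#' @export
key_slices <- function(n_slices, m) {
  if (m < 1L) cyclo_stop("m must be >= 1", "cyclo_parameter_error")
  sort(unique(c(seq(1L, n_slices, by = m), n_slices)))
}

#' Internal contours at all depth levels of one slice
#'
#' Each complete field line is represented as a cubic spline through its
#' points (natural end conditions, cumulative chord-length parameter) and
#' sampled at the absolute depths `c/(C-1) * d_i` along it. For each
#' depth level a closed periodic cubic spline is then fitted through the
#' sampled points, taken in the cyclic order of surviving line indices
#' (gaps left by removed lines are bridged by the spline), and resampled
#' to exactly `n_points` equidistant points starting at the sample from
#' the first surviving line.
#'
#' @param lines complete `field_line`s from [trace_all()].
#' @param n_levels C, number of depth levels.
#' @param n_points I, points per output contour.
#' @return List of `n_levels` contours (`n_points` x 2 matrices), inner
#'   (0%) first.
#' @export
internal_contours <- function(lines, n_levels, n_points) {
  if (length(lines) < 4L)
    cyclo_stop("need at least 4 complete field lines to fit closed contours",
               "cyclo_meshing_failure")
  fracs <- depth_levels(n_levels) / 100
  ## sample every line at every relative depth -> [line, level, xy]
  samples <- vapply(lines, function(ln) {
    pts <- ln$points
    tt <- cum_arc_length(pts, closed = FALSE)
    d <- tt[length(tt)]
    at <- fracs * d
    if (nrow(pts) >= 4L) {
      fx <- stats::splinefun(tt, pts[, 1L], method = "natural")
      fy <- stats::splinefun(tt, pts[, 2L], method = "natural")
      cbind(fx(at), fy(at))
    } else {
      cbind(stats::approx(tt, pts[, 1L], xout = at)$y,
            stats::approx(tt, pts[, 2L], xout = at)$y)
    }
  }, matrix(0, n_levels, 2L))
  lapply(seq_len(n_levels), function(ci)
    spline_resample_closed(t(samples[ci, , ]), n_points))
}

#' Local wall thickness table
#'
#' Lengths `d_i` of the complete field lines, one row per surviving line,
#' as a diagnostic table.
#'
#' @param lines_by_slice named list (names = slice indices) of lists of
#'   complete `field_line`s; a plain list of lines is also accepted.
#' @return data.frame with columns `slice`, `index`, `thickness` (px).
#' @export
local_thickness_map <- function(lines_by_slice) {
  if (length(lines_by_slice) && inherits(lines_by_slice[[1L]], "field_line"))
    lines_by_slice <- list(`NA` = lines_by_slice)
  do.call(rbind, lapply(names(lines_by_slice), function(h) {
    lns <- lines_by_slice[[h]]
    data.frame(slice = as.integer(h),
               index = vapply(lns, `[[`, 0L, "index"),
               thickness = vapply(lns, `[[`, 0, "length"))
  }))
}

#' Interpolate key-slice contours across all slices
#'
#' For every point index i and depth level c, natural cubic splines are
#' fitted through the key-slice coordinates `(x(h), y(h))` and evaluated
#' at every slice `h = 1 .. n_slices`; key-slice contours are reproduced
#' exactly at their own slice. The result is the full grid of re-slicing
#' surface points.
#'
#' @param key_contours named list (names = 1-based key slice indices) of
#'   per-slice contour lists as returned by [internal_contours()]; all
#'   with the same C and I, start indices aligned by the pairing rule.
#' @param n_slices H, total number of slices.
#' @return An object of class `reslicing_set`: list with `coords` (array
#'   `[I, 2, H, C]`), `perimeters` (H x C matrix, px, unrounded),
#'   `n_points`, `n_slices`, `n_levels`, `key_slices`.
#' @export
interpolate_sections <- function(key_contours, n_slices) {
  keys <- sort(as.integer(names(key_contours)))
  if (length(keys) < 1L || keys[1L] != 1L || keys[length(keys)] != n_slices)
    cyclo_stop("key slices must include the first and last slice",
               "cyclo_contract_error")
  key_contours <- key_contours[as.character(keys)]
  C <- length(key_contours[[1L]])
  I <- nrow(key_contours[[1L]][[1L]])
  ok <- vapply(key_contours, function(sl)
    length(sl) == C && all(vapply(sl, nrow, 0L) == I), TRUE)
  if (!all(ok))
    cyclo_stop("all key slices must have the same C and I", "cyclo_contract_error")
  coords <- array(NA_real_, c(I, 2L, n_slices, C))
  hh <- seq_len(n_slices)
  for (ci in seq_len(C)) {
    ## key coordinates as [key, I] matrices per axis
    xs <- t(vapply(key_contours, function(sl) sl[[ci]][, 1L], numeric(I)))
    ys <- t(vapply(key_contours, function(sl) sl[[ci]][, 2L], numeric(I)))
    for (ii in seq_len(I)) {
      if (length(keys) >= 2L) {
        coords[ii, 1L, , ci] <-
          stats::splinefun(keys, xs[, ii], method = "natural")(hh)
        coords[ii, 2L, , ci] <-
          stats::splinefun(keys, ys[, ii], method = "natural")(hh)
      } else {
        coords[ii, 1L, , ci] <- xs[, ii]
        coords[ii, 2L, , ci] <- ys[, ii]
      }
    }
  }
  perims <- matrix(NA_real_, n_slices, C)
  for (h in hh) for (ci in seq_len(C))
    perims[h, ci] <- contour_perimeter(coords[, , h, ci])
  structure(list(coords = coords, perimeters = perims, n_points = I,
                 n_slices = n_slices, n_levels = C, key_slices = keys),
            class = "reslicing_set")
}

#' @export
print.reslicing_set <- function(x, ...) {
  cat(sprintf(
    "re-slicing surface set: I=%d points, H=%d slices, C=%d depth levels (%d key slices)\n",
    x$n_points, x$n_slices, x$n_levels, length(x$key_slices)))
  invisible(x)
}

#' Count nesting violations between consecutive depth levels
#'
#' For every slice and every depth level c < C, counts vertices of
#' contour c that are not inside the polygon of contour c + 1. A valid
#' set of onion-like surfaces has zero escapes.
#'
#' @param surfaces a `reslicing_set`.
#' @param tol outward tolerance in pixels (0 = strict containment);
#'   vertices within `tol` of the enclosing polygon are not counted.
#' @return Integer: total number of escaped vertices.
#' @export
count_nesting_escapes <- function(surfaces, tol = 0) {
  esc <- 0L
  for (h in seq_len(surfaces$n_slices)) {
    for (ci in seq_len(surfaces$n_levels - 1L)) {
      inner <- surfaces$coords[, , h, ci]
      outer <- surfaces$coords[, , h, ci + 1L]
      out <- !point_in_polygon(inner, outer, boundary = TRUE)
      if (tol > 0 && any(out)) {
        grown <- shrink_or_grow(outer, tol)
        out <- out & !point_in_polygon(inner, grown, boundary = TRUE)
      }
      esc <- esc + sum(out)
    }
  }
  esc
}

## offset a convex-ish closed contour outward (d > 0) or inward (d < 0)
## along vertex normals from its centroid -- only used for tolerance in
## nesting checks on noisy contours
shrink_or_grow <- function(xy, d) {
  ctr <- colMeans(xy)
  v <- sweep(xy, 2L, ctr)
  r <- sqrt(rowSums(v^2))
  xy + v / r * d
}

#' Serialize a re-slicing surface set
#'
#' Writes `surfaces` to a single `.rds` archive plus a JSON sidecar
#' header carrying the grid dimensions and any parameters supplied, for
#' provenance.
#'
#' @param surfaces a `reslicing_set`.
#' @param path output `.rds` path; the header goes to `<path>.json`.
#' @param params optional named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_surfaces <- function(surfaces, path, params = list()) {
  saveRDS(surfaces, path)
  hdr <- c(list(n_points = surfaces$n_points, n_slices = surfaces$n_slices,
                n_levels = surfaces$n_levels,
                key_slices = surfaces$key_slices,
                layout = "coords[point, xy, slice, level]"),
           params)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
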