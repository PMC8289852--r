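# Opening, stretching and stacking contours into 2D cycloramas; probing
# the image volume; inverse mapping from cyclorama cells back to voxels.

#' Open a closed contour at azimuth pi
#'
#' Densely resamples the contour (via its periodic spline) to `n` points
#' -- by default its perimeter in pixels, rounded -- and cyclically
#' rotates it so that index 1 is the point whose azimuth about the
#' rotation axis `origin` is closest to pi radians (the leftmost
#' direction); ties are broken by the lowest pre-rotation index.
#' Increasing index then follows increasing azimuth for counter-clockwise
#' contours.
#'
#' @param xy contour vertices (closed, counter-clockwise).
#' @param origin rotation axis `(ox, oy)`, strictly inside the contour.
#' @param n number of output points; default `round(perimeter)`.
#' @param reverse reverse the column direction (clockwise opening).
#' @return n x 2 matrix starting at the azimuth-pi point, with the
#'   azimuths attached as attribute `"azimuth"` (radians in `[0, 2pi)`).
#' @export
open_contour <- function(xy, origin, n = NULL, reverse = FALSE) {
  xy <- as_xy(xy)
  if (!point_in_polygon(origin, xy, boundary = FALSE))
    cyclo_stop("rotation axis must lie strictly inside the contour",
               "cyclo_opening_error")
  if (is.null(n)) n <- max(3L, as.integer(round(contour_perimeter(xy))))
  dense <- spline_resample_closed(xy, n)
  if (reverse)
    dense <- dense[c(1L, rev(seq_len(n)[-1L])), , drop = FALSE]
  theta <- atan2(dense[, 2L] - origin[2L], dense[, 1L] - origin[1L]) %% (2 * pi)
  gap <- abs(theta - pi)  # azimuth distance to pi (theta in [0, 2pi))
  ## ties (within 1e-6 rad) resolve to the lowest pre-rotation index
  out <- rotate_start(dense, which.min(round(gap, 6L)))
  attr(out, "azimuth") <-
    atan2(out[, 2L] - origin[2L], out[, 1L] - origin[1L]) %% (2 * pi)
  out
}

#' Reference cyclorama length
#'
#' The longest contour in the surface set fixes the common length of all
#' 2D cycloramas: `L = max over (h, c)` of the rounded contour perimeter
#' in pixels. All shorter contours are stretched to this length.
#'
#' @param surfaces a `reslicing_set`.
#' @return Integer L.
#' @export
reference_length <- function(surfaces) {
  as.integer(max(round(surfaces$perimeters)))
}

#' Stretch an opened contour to the reference length
#'
#' Uniformly resamples the opened contour with exactly `L` points
#' equidistant by arc length, starting at its index-1 point, so every
#' contour fills a cyclorama row of the same length. The induced monotone
#' index map `i(l)` from stretched to original indices is attached as
#' attribute `"index_map"`.
#'
#' @param opened contour from [open_contour()] with `n <= L` points.
#' @param L reference length from [reference_length()].
#' @return L x 2 matrix of source positions.
#' @export
stretch_contour <- function(opened, L) {
  n <- nrow(opened)
  out <- resample_equal_chords(opened, L, closed = TRUE)
  attr(out, "index_map") <- pmin(n, 1L + floor((seq_len(L) - 1L) * n / L))
  out
}

## bilinear (or nearest) sample of one slice matrix [rows x cols] at
## continuous positions; out-of-bounds positions get `fill`
sample_slice <- function(slice, x, y, interp = "bilinear", fill = 0) {
  rows <- nrow(slice); cols <- ncol(slice)
  inb <- x >= 1 & x <= cols & y >= 1 & y <= rows
  g <- rep(as.numeric(fill), length(x))
  if (any(inb)) {
    if (interp == "nearest") {
      g[inb] <- slice[cbind(round(y[inb]), round(x[inb]))]
    } else {
      g[inb] <- pracma::interp2(seq_len(cols), seq_len(rows), slice,
                                x[inb], y[inb], method = "linear")
    }
  }
  list(values = g, n_oob = sum(!inb))
}

#' Probe the image volume along all re-slicing surfaces
#'
#' Builds the 3D cyclorama: every contour `(h, c)` is opened at azimuth
#' pi about `origin`, stretched to the reference length L, and the slice
#' `h` of the volume is sampled at the resulting source positions. The
#' source coordinate tables are retained at full precision so the
#' mapping can be inverted exactly to rounding.
#'
#' @param volume numeric array `[rows, cols, H]` (see [read_stack()]).
#' @param surfaces a `reslicing_set` with `n_slices == H`.
#' @param origin rotation axis `(ox, oy)`, constant across slices and
#'   depths; default: centroid of the inner contour of the first slice.
#' @param L reference length; default [reference_length()] of `surfaces`.
#' @param interp `"bilinear"` (default) or `"nearest"` (for label volumes).
#' @param fill grey value for out-of-bounds probes.
#' @param reverse reverse the column direction.
#' @param verbose report out-of-bounds probe counts.
#' @return An object of class `cyclorama`: list with `values` (array
#'   `[L, H, C]` of grey values), `sx`, `sy` (same-shaped source
#'   coordinate tables), `L`, `origin`, `interp`, `fill`, `n_oob`,
#'   `dim_volume`.
#' @export
probe_volume <- function(volume, surfaces, origin = NULL, L = NULL,
                         interp = c("bilinear", "nearest"), fill = 0,
                         reverse = FALSE, verbose = FALSE) {
  interp <- match.arg(interp)
  H <- surfaces$n_slices; C <- surfaces$n_levels
  if (dim(volume)[3L] != H)
    cyclo_stop("volume slice count does not match the surface set",
               "cyclo_contract_error")
  if (is.null(origin)) origin <- colMeans(surfaces$coords[, , 1L, 1L])
  if (is.null(L)) L <- reference_length(surfaces)
  ## the rotation axis must be inside every inner contour
  for (h in seq_len(H))
    if (!point_in_polygon(origin, surfaces$coords[, , h, 1L],
                          boundary = FALSE)) {
      warning(sprintf("rotation axis outside the inner contour of slice %d", h))
      cyclo_stop("rotation axis must lie inside every inner boundary contour",
                 "cyclo_opening_error")
    }
  G <- array(NA_real_, c(L, H, C))
  SX <- array(NA_real_, c(L, H, C))
  SY <- array(NA_real_, c(L, H, C))
  n_oob <- 0L
  for (ci in seq_len(C)) {
    for (h in seq_len(H)) {
      nhc <- max(3L, as.integer(round(surfaces$perimeters[h, ci])))
      opened <- open_contour(surfaces$coords[, , h, ci], origin,
                             n = min(nhc, L), reverse = reverse)
      st <- stretch_contour(opened, L)
      SX[, h, ci] <- st[, 1L]; SY[, h, ci] <- st[, 2L]
      smp <- sample_slice(volume[, , h], st[, 1L], st[, 2L], interp, fill)
      G[, h, ci] <- smp$values
      n_oob <- n_oob + smp$n_oob
    }
  }
  cyclo_log(verbose, "probed %d points, %d out of bounds (filled with %g)",
            length(G), n_oob, fill)
  structure(list(values = G, sx = SX, sy = SY, L = as.integer(L),
                 origin = as.numeric(origin), interp = interp,
                 fill = fill, n_oob = n_oob, dim_volume = dim(volume)),
            class = "cyclorama")
}

#' @export
print.cyclorama <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "3D cyclorama: L=%d x H=%d x C=%d, origin (%.1f, %.1f), %s probing, %d out-of-bounds\n",
    d[1L], d[2L], d[3L], x$origin[1L], x$origin[2L], x$interp, x$n_oob))
  invisible(x)
}

#' Map cyclorama cells back into the voxel grid
#'
#' Each cyclorama cell `(l, h, c)` maps back to the voxel
#' `(row = round(sy), col = round(sx), slice = h)` through the stored
#' source coordinate tables; optionally every mapped voxel is dilated to
#' an axis-aligned cube (e.g. edge 5 for region-growing seed volumes),
#' clipped at the volume borders. The result is a binary mask with the
#' original volume's dimensions, suitable as a seed image for external
#' segmentation tools.
#'
#' @param cells n x 3 matrix (or data.frame) of 1-based cyclorama
#'   indices `(l, h, c)`.
#' @param cyclo a `cyclorama` (must retain its coordinate tables).
#' @param cube odd cube edge in voxels (1 = single voxels).
#' @return Integer 0/1 array with `cyclo$dim_volume` dimensions.
#' @export
inverse_map <- function(cells, cyclo, cube = 1L) {
  cells <- as.matrix(cells)
  if (length(cells) && (ncol(cells) != 3L))
    cyclo_stop("cells must have columns (l, h, c)", "cyclo_contract_error")
  dv <- cyclo$dim_volume
  mask <- array(0L, dv)
  if (nrow(cells) == 0L) return(mask)
  idx <- cbind(cells[, 1L], cells[, 2L], cells[, 3L])
  dcy <- dim(cyclo$sx)
  if (any(idx < 1L) || any(idx[, 1L] > dcy[1L]) || any(idx[, 2L] > dcy[2L]) ||
      any(idx[, 3L] > dcy[3L]))
    cyclo_stop("cyclorama cell index out of range", "cyclo_contract_error")
  col <- round(cyclo$sx[idx]); row <- round(cyclo$sy[idx]); sl <- idx[, 2L]
  half <- (as.integer(cube) - 1L) %/% 2L
  off <- -half:half
  for (dr in off) for (dc in off) for (ds in off) {
    r <- row + dr; cc <- col + dc; s <- sl + ds
    ok <- r >= 1L & r <= dv[1L] & cc >= 1L & cc <= dv[2L] &
      s >= 1L & s <= dv[3L]
    if (any(ok)) mask[cbind(r[ok], cc[ok], s[ok])] <- 1L
  }
  mask
}
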