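# Shared low-level helpers: condition classes, polyline resampling,
# closed-curve splines, segment/polygon intersection.

cyclo_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "cyclorama_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

cyclo_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}

as_xy <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || !is.numeric(xy))
    cyclo_stop("contour must be an n x 2 numeric matrix of (x, y) positions",
               "cyclo_invalid_contour")
  storage.mode(xy) <- "double"
  unname(xy)
}

## drop consecutive duplicate vertices (and a duplicated closing vertex)
dedupe_vertices <- function(xy, tol = 1e-12) {
  n <- nrow(xy)
  if (n < 2L) return(xy)
  keep <- c(TRUE, rowSums((xy[-1L, , drop = FALSE] -
                             xy[-n, , drop = FALSE])^2) > tol^2)
  xy <- xy[keep, , drop = FALSE]
  n <- nrow(xy)
  if (n > 1L && sum((xy[1L, ] - xy[n, ])^2) <= tol^2)
    xy <- xy[-n, , drop = FALSE]
  xy
}

## cumulative arc length along a polyline; closed curves append the
## closing segment, so the last entry is the perimeter
cum_arc_length <- function(xy, closed = TRUE) {
  pts <- if (closed) rbind(xy, xy[1L, ]) else xy
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

#' Signed area of a polygon
#'
#' Shoelace signed area in image coordinates (x = column, y = row). The
#' package's "counter-clockwise" convention is signed area > 0 under this
#' formula; with y increasing downwards this traversal appears clockwise on
#' screen and follows increasing azimuth `atan2(y - oy, x - ox)`.
#'
#' @param xy n x 2 matrix of vertices (closed polygon, last edge implicit).
#' @return Signed area (pixels^2).
#' @export
signed_area <- function(xy) {
  xy <- as_xy(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygonal perimeter
#'
#' Total arc length of the polyline through the vertices, in pixels.
#'
#' @param xy n x 2 vertex matrix.
#' @param closed include the closing segment (default `TRUE`).
#' @return Perimeter in pixels (not rounded).
#' @export
contour_perimeter <- function(xy, closed = TRUE) {
  xy <- as_xy(xy)
  s <- cum_arc_length(xy, closed = closed)
  s[length(s)]
}

#' Resample a polyline at equidistant arc-length positions
#'
#' Piecewise-linear resampling: the output vertices sit on the input
#' polyline at arc positions `0, P/n, 2P/n, ...` (closed; `P` = perimeter)
#' or at `0 .. P` inclusive (open), measured along the input polyline.
#'
#' @param xy n x 2 vertex matrix.
#' @param n number of output points.
#' @param closed treat the polyline as a closed loop.
#' @return n x 2 matrix.
#' @export
resample_polyline <- function(xy, n, closed = TRUE) {
  xy <- dedupe_vertices(as_xy(xy))
  if (nrow(xy) < 2L)
    cyclo_stop("cannot resample a degenerate polyline", "cyclo_invalid_contour")
  s <- cum_arc_length(xy, closed = closed)
  total <- s[length(s)]
  if (total <= 0)
    cyclo_stop("zero-perimeter polyline", "cyclo_invalid_contour")
  pts <- if (closed) rbind(xy, xy[1L, ]) else xy
  targets <- if (closed) total * (seq_len(n) - 1L) / n
             else seq(0, total, length.out = n)
  cbind(stats::approx(s, pts[, 1L], xout = targets, ties = "ordered")$y,
        stats::approx(s, pts[, 2L], xout = targets, ties = "ordered")$y)
}

## equal-chord resampling: iterate arc-length resampling to its fixed
## point, where consecutive vertex spacings (= the output polygon's own
## arc spacing) are uniform; this makes resampling idempotent
resample_equal_chords <- function(xy, n, closed = TRUE, tol = 1e-9,
                                  max_iter = 30L) {
  cur <- resample_polyline(xy, n, closed = closed)
  for (it in seq_len(max_iter)) {
    nxt <- resample_polyline(cur, n, closed = closed)
    moved <- max(abs(nxt - cur))
    cur <- nxt
    if (moved < tol) break
  }
  cur
}

## periodic cubic spline through the vertices of a closed contour,
## parameterised by cumulative chord length, evaluated at n equidistant
## arc positions starting exactly at vertex 1
spline_resample_closed <- function(xy, n, densify = 12L) {
  xy <- dedupe_vertices(as_xy(xy))
  if (nrow(xy) < 3L)
    cyclo_stop("closed contour needs at least 3 distinct points",
               "cyclo_invalid_contour")
  s <- cum_arc_length(xy, closed = TRUE)
  pts <- rbind(xy, xy[1L, ])
  fx <- stats::splinefun(s, pts[, 1L], method = "periodic")
  fy <- stats::splinefun(s, pts[, 2L], method = "periodic")
  m <- max(4L * nrow(xy), densify * n)
  tt <- seq(0, s[length(s)], length.out = m + 1L)[-(m + 1L)]
  dense <- cbind(fx(tt), fy(tt))
  resample_equal_chords(dense, n, closed = TRUE)
}

## rotate point order of a closed contour so row `k` becomes row 1
rotate_start <- function(xy, k) {
  n <- nrow(xy)
  if (k == 1L) return(xy)
  xy[c(k:n, seq_len(k - 1L)), , drop = FALSE]
}

## first intersection of segment p0->p1 with the edges of polygon `poly`
## (closed by default; closed = FALSE treats it as an open polyline), as
## the smallest parameter t in [0, 1]; NULL if none
segment_polygon_intersection <- function(p0, p1, poly, closed = TRUE) {
  if (closed) {
    a <- poly
    b <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  } else {
    a <- poly[-nrow(poly), , drop = FALSE]
    b <- poly[-1L, , drop = FALSE]
  }
  d <- p1 - p0
  e1 <- b[, 1L] - a[, 1L]; e2 <- b[, 2L] - a[, 2L]
  denom <- d[1L] * e2 - d[2L] * e1
  wx <- a[, 1L] - p0[1L]; wy <- a[, 2L] - p0[2L]
  t <- (wx * e2 - wy * e1) / denom   # along the segment
  u <- (wx * d[2L] - wy * d[1L]) / denom   # along the edge
  ok <- is.finite(t) & is.finite(u) & t >= -1e-12 & t <= 1 + 1e-12 &
    u >= -1e-12 & u <= 1 + 1e-12
  if (!any(ok)) return(NULL)
  tmin <- min(t[ok])
  tmin <- min(max(tmin, 0), 1)
  list(t = tmin, point = p0 + tmin * d)
}
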