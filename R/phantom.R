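# Synthetic deformed-tube phantoms with analytic boundary contours and
# ground-truth markers at known azimuth / relative depth, used to verify
# the unrolling pipeline end to end.

#' Specify a synthetic tube phantom
#'
#' Describes a roughly vertical tube rendered into a grey-value stack.
#' Radii may taper linearly along the stack and the cross section may be
#' deformed sinusoidally: `r(theta) = R * (1 + amp * cos(lobes * (theta -
#' phase(h))))` with the phase advancing linearly by `twist` radians over
#' the stack. Markers are bright blobs placed at an exact azimuth and
#' relative wall depth (0 = inner boundary, 1 = outer), spanning a slice
#' range.
#'
#' @param rows,cols,n_slices volume dimensions (pixels / slices).
#' @param center tube axis `(x, y)`; default volume centre.
#' @param inner_radius,outer_radius radii in pixels; length 1 (constant)
#'   or 2 (`c(first, last)` slice, linear taper).
#' @param amp deformation amplitude (fraction of radius, 0 = circular).
#' @param lobes number of sinusoidal lobes k.
#' @param twist total deformation phase change over the stack (radians).
#' @param markers data.frame with columns `azimuth_deg`, `depth`
#'   (fraction in `[0, 1]`), `h_lo`, `h_hi` (1-based slice range),
#'   `intensity`; optional `radius` (blob radius px, default 3).
#' @param wall,background grey values of the wall and everything else.
#' @param noise_sd additive Gaussian noise sigma (grey values); default 0
#'   so phantoms are deterministic without a seed.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param bits bit depth of the rendered stack (8 or 16).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(rows = 256L, cols = 256L, n_slices = 21L,
                         center = NULL, inner_radius = 50, outer_radius = 90,
                         amp = 0, lobes = 0L, twist = 0,
                         markers = NULL, wall = 170, background = 30,
                         noise_sd = 0, seed = 1L, bits = 8L) {
  if (is.null(center)) center <- c((cols + 1) / 2, (rows + 1) / 2)
  if (length(inner_radius) == 1L) inner_radius <- rep(inner_radius, 2L)
  if (length(outer_radius) == 1L) outer_radius <- rep(outer_radius, 2L)
  spec <- list(rows = as.integer(rows), cols = as.integer(cols),
               n_slices = as.integer(n_slices), center = as.numeric(center),
               inner_radius = as.numeric(inner_radius),
               outer_radius = as.numeric(outer_radius),
               amp = as.numeric(amp), lobes = as.integer(lobes),
               twist = as.numeric(twist), markers = markers,
               wall = wall, background = background,
               noise_sd = as.numeric(noise_sd), seed = as.integer(seed),
               bits = as.integer(bits))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  frac <- c(0, 0.5, 1)
  rin <- spec$inner_radius[1L] + frac * diff(spec$inner_radius)
  rout <- spec$outer_radius[1L] + frac * diff(spec$outer_radius)
  if (any(rin * (1 + abs(spec$amp)) >= rout * (1 - abs(spec$amp))))
    cyclo_stop("inner radius must stay below outer radius everywhere (deformation included)",
               "cyclo_spec_error")
  if (!is.null(spec$markers)) {
    m <- spec$markers
    need <- c("azimuth_deg", "depth", "h_lo", "h_hi", "intensity")
    if (!all(need %in% names(m)))
      cyclo_stop(paste("markers need columns:", paste(need, collapse = ", ")),
                 "cyclo_spec_error")
    if (any(m$depth < 0 | m$depth > 1))
      cyclo_stop("marker depth outside the wall (must be in [0, 1])",
                 "cyclo_spec_error")
    if (any(m$h_lo < 1L | m$h_hi > spec$n_slices | m$h_lo > m$h_hi))
      cyclo_stop("marker slice range outside the stack", "cyclo_spec_error")
  }
  invisible(spec)
}

## deformed radius at azimuth theta on slice h (1-based)
phantom_radius <- function(spec, which, theta, h) {
  f <- if (spec$n_slices > 1L) (h - 1) / (spec$n_slices - 1) else 0
  base <- if (which == "inner")
    spec$inner_radius[1L] + f * diff(spec$inner_radius)
  else
    spec$outer_radius[1L] + f * diff(spec$outer_radius)
  phase <- spec$twist * f
  if (spec$amp != 0 && spec$lobes > 0L)
    base * (1 + spec$amp * cos(spec$lobes * (theta - phase)))
  else
    rep(base, length(theta))
}

#' Analytic boundary contours of a phantom slice
#'
#' Exact (not re-segmented) inner and outer boundary contours of slice
#' `h`, emitted directly from the phantom's radius functions so meshing
#' tests are decoupled from rasterization error.
#'
#' @param spec a `phantom_spec`.
#' @param h 1-based slice index.
#' @param n_points points per contour.
#' @return List with `slice`, `inner`, `outer` (n x 2 matrices,
#'   counter-clockwise).
#' @export
phantom_boundaries <- function(spec, h, n_points = 400L) {
  theta <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  mk <- function(which) {
    r <- phantom_radius(spec, which, theta, h)
    cbind(spec$center[1L] + r * cos(theta), spec$center[2L] + r * sin(theta))
  }
  list(slice = as.integer(h), inner = mk("inner"), outer = mk("outer"))
}

## ground-truth in-plane position of a marker on slice h
marker_position <- function(spec, azimuth_deg, depth, h) {
  th <- azimuth_deg * pi / 180
  rin <- phantom_radius(spec, "inner", th, h)
  rout <- phantom_radius(spec, "outer", th, h)
  rho <- rin + depth * (rout - rin)
  c(spec$center[1L] + rho * cos(th), spec$center[2L] + rho * sin(th))
}

#' Render a phantom tube stack
#'
#' Rasterizes the phantom into a grey-value volume, embeds the markers at
#' their exact azimuth/depth positions, optionally adds seeded Gaussian
#' noise, and returns the volume together with analytic boundary contours
#' on the requested key slices and the ground-truth marker table.
#'
#' @param spec a `phantom_spec`.
#' @param key_interval emit analytic boundary contours on every
#'   `key_interval`-th slice (plus the last); see [key_slices()].
#' @param n_contour_points points per emitted boundary contour.
#' @return List with `volume` (numeric array `[rows, cols, H]`, integer
#'   grey values), `bits`, `contours` (list of per-key-slice boundary
#'   pairs as in [phantom_boundaries()]), `markers` (data.frame with the
#'   ground-truth azimuth, depth, slice range and rendered position).
#' @export
make_tube <- function(spec, key_interval = 20L, n_contour_points = 400L) {
  validate_phantom_spec(spec)
  H <- spec$n_slices
  xs <- matrix(seq_len(spec$cols), spec$rows, spec$cols, byrow = TRUE)
  ys <- matrix(seq_len(spec$rows), spec$rows, spec$cols)
  dx <- xs - spec$center[1L]; dy <- ys - spec$center[2L]
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  vol <- array(as.numeric(spec$background), c(spec$rows, spec$cols, H))
  for (h in seq_len(H)) {
    rin <- phantom_radius(spec, "inner", th, h)
    rout <- phantom_radius(spec, "outer", th, h)
    sl <- vol[, , h]
    sl[rr >= rin & rr <= rout] <- spec$wall
    vol[, , h] <- sl
  }
  gt <- NULL
  if (!is.null(spec$markers)) {
    m <- spec$markers
    if (is.null(m$radius)) m$radius <- 3
    pos <- matrix(NA_real_, nrow(m), 2L)
    for (j in seq_len(nrow(m))) {
      for (h in m$h_lo[j]:m$h_hi[j]) {
        p <- marker_position(spec, m$azimuth_deg[j], m$depth[j], h)
        if (h == m$h_lo[j]) pos[j, ] <- p
        hit <- (xs - p[1L])^2 + (ys - p[2L])^2 <= m$radius[j]^2
        sl <- vol[, , h]
        sl[hit] <- m$intensity[j]
        vol[, , h] <- sl
      }
    }
    gt <- cbind(m, x = pos[, 1L], y = pos[, 2L])
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + stats::rnorm(length(vol), sd = spec$noise_sd)
  }
  vmax <- 2^spec$bits - 1
  vol <- round(pmin(pmax(vol, 0), vmax))
  keys <- key_slices(H, key_interval)
  contours <- lapply(keys, phantom_boundaries, spec = spec,
                     n_points = n_contour_points)
  names(contours) <- keys
  list(volume = vol, bits = spec$bits, contours = contours, markers = gt)
}

#' Preset phantoms
#'
#' Convenience constructors for the phantoms the test-bench uses:
#' `"concentric"` -- straight circular tube; `"deformed"` -- sinusoidal
#' three-lobed deformation (amplitude 0.15) with a gentle twist along
#' the stack, rendered at 512 x 512 x 61; `"marker-sheet"` -- concentric
#' tube with 12 markers at relative depths 0.25 / 0.50 / 0.75 and
#' azimuths 0 / 90 / 180 / 270 degrees.
#'
#' @param preset one of `"concentric"`, `"deformed"`, `"marker-sheet"`.
#' @param seed RNG seed stored in the spec (used only when noise is
#'   enabled).
#' @param ... overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(preset = c("concentric", "deformed",
                                      "marker-sheet"),
                           seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    concentric = list(rows = 256L, cols = 256L, n_slices = 21L,
                      inner_radius = 50, outer_radius = 90),
    deformed = list(rows = 512L, cols = 512L, n_slices = 61L,
                    inner_radius = 100, outer_radius = 180,
                    amp = 0.15, lobes = 3L, twist = pi / 4),
    `marker-sheet` = {
      mk <- expand.grid(azimuth_deg = c(0, 90, 180, 270),
                        depth = c(0.25, 0.5, 0.75))
      mk$h_lo <- 8L; mk$h_hi <- 14L; mk$intensity <- 255
      list(rows = 256L, cols = 256L, n_slices = 21L,
           inner_radius = 50, outer_radius = 90, markers = mk)
    })
  do.call(phantom_spec, utils::modifyList(c(args, list(seed = seed)),
                                          list(...)))
}

#' Generate a C-shaped open-boundary sheet phantom (experimental)
#'
#' Exercises the open-boundary extension path (digital flattening of
#' thick sheets): a half-annulus whose inner and outer boundaries are
#' open arcs. Returns the open boundary polylines and the closed region
#' polygon of the sheet; [trace_sheet_line()] traces field lines on it.
#' This path is experimental and not part of the tube pipeline.
#'
#' @param spec a `phantom_spec` (radii and centre are used).
#' @param arc arc span in radians (default `pi`, a half annulus).
#' @param n_points points per boundary arc.
#' @return List of class `sheet_phantom` with `inner`, `outer` (open
#'   n x 2 polylines, same direction) and `region` (closed polygon).
#' @export
make_c_shape <- function(spec, arc = pi, n_points = 100L) {
  if (spec$outer_radius[1L] - spec$inner_radius[1L] <= 0)
    cyclo_stop("zero-thickness sheet", "cyclo_spec_error")
  theta <- seq(-arc / 2, arc / 2, length.out = n_points)
  mk <- function(r) cbind(spec$center[1L] + r * cos(theta),
                          spec$center[2L] + r * sin(theta))
  inner <- mk(spec$inner_radius[1L])
  outer <- mk(spec$outer_radius[1L])
  structure(list(inner = inner, outer = outer,
                 region = rbind(inner, outer[rev(seq_len(n_points)), ])),
            class = "sheet_phantom")
}

#' Trace a field line on an open sheet (experimental)
#'
#' Same construction as [trace_field_line()] but for open boundaries:
#' the charge window is clamped at the arc ends instead of wrapping, the
#' containment test uses the sheet's region polygon, and a line is
#' complete when its exit segment crosses the outer arc.
#'
#' @param sheet a `sheet_phantom`.
#' @param i inner arc point index.
#' @param params a `field_params` object (`n_points` ignored; the arcs
#'   fix the point count).
#' @return A `field_line` (status `"complete"`, `"stray"` or
#'   `"collapsed"`).
#' @export
trace_sheet_line <- function(sheet, i, params) {
  n <- nrow(sheet$inner)
  inside <- function(p) point_in_polygon(p, sheet$region, boundary = FALSE)
  ## one-sided tangent at the arc ends
  i2 <- min(i + 1L, n); i1 <- if (i2 == i) i - 1L else i
  u <- sheet$inner[i2, ] - sheet$inner[i1, ]
  perp <- c(u[2L], -u[1L]) / sqrt(sum(u^2))
  p0 <- sheet$inner[i, ]
  nrm <- NULL
  for (s in c(1, -1)) if (inside(p0 + params$delta * s * perp)) nrm <- s * perp
  if (is.null(nrm))
    return(structure(list(index = i, points = matrix(p0, ncol = 2L),
                          status = "collapsed", length = NA_real_,
                          variance = 0), class = "field_line"))
  J <- max(1L, i - params$window):min(n, i + params$window)
  pts <- matrix(NA_real_, params$k_max + 1L, 2L)
  pts[1L, ] <- p0; pts[2L, ] <- p0 + params$delta * nrm
  k <- 2L; status <- "stray"
  while (TRUE) {
    p <- pts[k, ]
    if (!inside(p)) {
      hit <- segment_polygon_intersection(pts[k - 1L, ], p, sheet$outer,
                                          closed = FALSE)
      status <- if (!is.null(hit)) "complete" else "stray"
      if (!is.null(hit)) pts[k, ] <- hit$point
      break
    }
    if (k > params$k_max) break
    din <- sweep(sheet$inner[J, , drop = FALSE], 2L, p, "-") * -1
    dout <- sweep(sheet$outer[J, , drop = FALSE], 2L, p, "-") * -1
    rin <- sqrt(rowSums(din^2)); rout <- sqrt(rowSums(dout^2))
    if (min(rin, rout) < 1e-9) break
    E <- colSums(din / rin^3) - params$rigidity * colSums(dout / rout^3)
    nE <- sqrt(sum(E^2))
    if (nE <= 0) break
    pts[k + 1L, ] <- p + params$delta * E / nE
    k <- k + 1L
  }
  pts <- pts[seq_len(k), , drop = FALSE]
  v <- line_variance(pts)
  if (v < params$v_min && status != "complete") status <- "collapsed"
  structure(list(index = i, points = pts, status = status,
                 length = if (status == "complete")
                   sum(sqrt(rowSums(diff(pts)^2))) else NA_real_,
                 variance = v),
            class = "field_line")
}
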