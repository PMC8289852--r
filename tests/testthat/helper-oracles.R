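# Independent oracles and shared fixtures for the test suite. The
# oracles deliberately re-derive results with plain loops, independent of
# the package's vectorized implementations.

## even-odd (crossing number) point-in-polygon, straight from the rule
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

## brute-force arc-length resampler: walk the closed polyline segment by
## segment and emit points at multiples of perimeter/n
oracle_resample <- function(xy, n) {
  pts <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  total <- sum(seg)
  out <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    target <- (k - 1) * total / n
    acc <- 0
    for (s in seq_along(seg)) {
      if (acc + seg[s] >= target - 1e-12) {
        t <- if (seg[s] > 0) (target - acc) / seg[s] else 0
        out[k, ] <- pts[s, ] + t * (pts[s + 1, ] - pts[s, ])
        break
      }
      acc <- acc + seg[s]
    }
  }
  out
}

## do two open polylines intersect? plain O(n*m) segment pair test
oracle_polylines_cross <- function(a, b) {
  seg_cross <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    denom <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(denom) < 1e-14) return(FALSE)
    w <- q1 - p1
    t <- (w[1] * d2[2] - w[2] * d2[1]) / denom
    u <- (w[1] * d1[2] - w[2] * d1[1]) / denom
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      if (seg_cross(a[i, ], a[i + 1, ], b[j, ], b[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

circle_points <- function(n, r, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

## concentric circular annulus section: radii 20 / 40 about (128, 128)
concentric_section <- function(I = 200) {
  ctr <- c(128, 128)
  pair_boundaries(normalize_contour(circle_points(I, 20, ctr), I),
                  normalize_contour(circle_points(I, 40, ctr), I),
                  slice = 1L)
}

## ---- shared fixtures, computed once per test run --------------------
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_concentric_lines <- function() fixture("concentric_lines", function() {
  sec <- concentric_section(200)
  list(section = sec,
       lines = trace_all(sec, field_params(200, 15, 2, 1, 75, 50)))
})

## marker-sheet phantom unrolled at C = 5 (markers at depths .25/.5/.75)
fx_marker_unroll <- function() fixture("marker_unroll", function() {
  spec <- phantom_preset("marker-sheet")
  ph <- make_tube(spec, key_interval = 10L)
  cfg <- run_config(m = 10L, n_levels = 5L)
  surfaces <- mesh_sections(ph$contours, dim(ph$volume)[3], cfg)
  cyclo <- probe_volume(ph$volume, surfaces)
  list(spec = spec, phantom = ph, surfaces = surfaces, cyclo = cyclo)
})

## three-lobed sinusoidally deformed tube (amplitude 0.15) at full scale,
## meshed on every 20th slice and probed at C = 5 depth levels
fx_deformed_unroll <- function() fixture("deformed_unroll", function() {
  spec <- phantom_preset("deformed")
  ph <- make_tube(spec, key_interval = 20L)
  cfg <- run_config(m = 20L, n_levels = 5L)
  surfaces <- mesh_sections(ph$contours, dim(ph$volume)[3], cfg)
  cyclo <- probe_volume(ph$volume, surfaces)
  list(spec = spec, phantom = ph, surfaces = surfaces, cyclo = cyclo)
})

## bright cyclorama cells clustered into recovered markers: per depth
## level, split sorted azimuths at gaps > gap_deg; returns one row per
## cluster with the mean column, circular mean azimuth and depth level
recover_markers <- function(cyclo, center, thresh = 250, gap_deg = 20) {
  G <- cyclo$values
  C <- dim(G)[3]
  out <- NULL
  for (ci in seq_len(C)) {
    cells <- which(G[, , ci] >= thresh, arr.ind = TRUE)
    if (!nrow(cells)) next
    az <- atan2(cyclo$sy[cbind(cells[, 1], cells[, 2], ci)] - center[2],
                cyclo$sx[cbind(cells[, 1], cells[, 2], ci)] - center[1])
    az <- (az * 180 / pi) %% 360
    ord <- order(az)
    az_s <- az[ord]; l_s <- cells[ord, 1]
    gaps <- diff(az_s) > gap_deg
    grp <- cumsum(c(1, gaps))
    ## merge the wrap-around pair if first and last clusters touch mod 360
    if (max(grp) > 1 && (az_s[1] + 360 - az_s[length(az_s)]) <= gap_deg)
      grp[grp == max(grp)] <- 1
    L <- dim(G)[1]
    for (g in unique(grp)) {
      a <- az_s[grp == g] * pi / 180
      mean_az <- (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
      ## columns are circular: a cluster on the seam straddles 1 and L
      lphase <- 2 * pi * (l_s[grp == g] - 1) / L
      mean_l <- (atan2(mean(sin(lphase)), mean(cos(lphase))) %% (2 * pi)) *
        L / (2 * pi) + 1
      out <- rbind(out, data.frame(
        level = ci, depth = (ci - 1) / (C - 1), azimuth = mean_az,
        l = mean_l, n = sum(grp == g)))
    }
  }
  out
}

## smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
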