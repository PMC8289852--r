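# Virtual electrostatic field lines across an annulus section.
#
# Inner boundary points carry charge +1, outer boundary points carge
# -rigidity. A line starts at inner point i, takes a first step of length
# delta along the boundary normal (into the annulus), then repeatedly
# steps delta along the local field direction, the field being summed over
# a sliding window of 2w+1 charges per boundary centred at index i. Lines
# that fail to reach the outer boundary within k_max steps are "stray";
# lines whose point-scatter variance falls below v_min are "collapsed";
# both are discarded. The length of a complete line (final segment clipped
# at the outer polygon) is the local wall thickness d_i.

#' Field-line tracing parameters
#'
#' @param n_points I, points per boundary contour.
#' @param window w, half-width of the sliding charge window; the window
#'   holds `2 * window + 1` charges per boundary and must fit in the
#'   contour (`2w + 1 <= I`).
#' @param delta step (segment) size in pixels.
#' @param rigidity magnitude of the outer-boundary charges relative to the
#'   inner-boundary unit charges; larger values give stiffer (straighter)
#'   lines, smaller values more flexible lines.
#' @param k_max maximum number of steps before a line is declared stray.
#' @param v_min minimum point-scatter variance (pixel^2) below which a
#'   line is declared collapsed.
#' @return A `field_params` list.
#' @export
field_params <- function(n_points = 200L, window = 15L, delta = 2,
                         rigidity = 1, k_max = 75L, v_min = 50) {
  p <- list(n_points = as.integer(n_points), window = as.integer(window),
            delta = as.numeric(delta), rigidity = as.numeric(rigidity),
            k_max = as.integer(k_max), v_min = as.numeric(v_min))
  if (p$n_points < 3L) cyclo_stop("n_points must be >= 3", "cyclo_parameter_error")
  if (p$window < 1L) cyclo_stop("window must be >= 1", "cyclo_parameter_error")
  if (2L * p$window + 1L > p$n_points)
    cyclo_stop("charge window does not fit: need 2*window + 1 <= n_points",
               "cyclo_parameter_error")
  if (p$delta <= 0) cyclo_stop("delta must be > 0", "cyclo_parameter_error")
  if (p$rigidity <= 0) cyclo_stop("rigidity must be > 0", "cyclo_parameter_error")
  if (p$k_max < 1L) cyclo_stop("k_max must be >= 1", "cyclo_parameter_error")
  if (p$v_min < 0) cyclo_stop("v_min must be >= 0", "cyclo_parameter_error")
  structure(p, class = "field_params")
}

#' Cyclic charge-window indices
#'
#' The `2w + 1` cyclically contiguous contour indices centred at `i`
#' (1-based, modulo the contour size).
#'
#' @param i centre index (1..n_points).
#' @param w half-width.
#' @param n_points contour size I.
#' @return Integer vector of length `2w + 1`.
#' @export
window_indices <- function(i, w, n_points) {
  ((i - w - 1L):(i + w - 1L)) %% n_points + 1L
}

#' Boundary normal pointing into the annulus
#'
#' Unit vector perpendicular to the local tangent
#' `u_i = p[i+1] - p[i]` (cyclic) at inner boundary point `i`, with the
#' sign chosen so that `p[i] + delta * normal` lies inside the annulus.
#'
#' @param section an `annulus_section`.
#' @param i inner boundary point index (1-based).
#' @param delta probe step used to pick the sign, in pixels.
#' @return Unit 2-vector, or `NULL` when neither sign lands inside the
#'   annulus (e.g. `delta` exceeds the local wall thickness); callers
#'   treat that line as failed at start.
#' @export
inward_normal <- function(section, i, delta) {
  inner <- section$inner
  n <- nrow(inner)
  u <- inner[i %% n + 1L, ] - inner[i, ]
  nu <- sqrt(sum(u^2))
  if (nu <= 0) return(NULL)
  perp <- c(u[2L], -u[1L]) / nu
  for (s in c(1, -1)) {
    if (annulus_contains(inner[i, ] + delta * s * perp, section))
      return(s * perp)
  }
  NULL
}

#' Windowed electric field at a point
#'
#' Sum of inverse-square contributions from the `2w + 1` inner charges
#' (+1 each) and outer charges (-rigidity each) in the window centred at
#' contour index `i`. The physical prefactor 1/(4 pi eps0) is dropped:
#' steps use only the field direction.
#'
#' @param p length-2 position.
#' @param section an `annulus_section`.
#' @param i index of the line being traced (selects the window).
#' @param params a `field_params` object.
#' @return Field 2-vector (unnormalized).
#' @export
electric_field <- function(p, section, i, params) {
  J <- window_indices(i, params$window, nrow(section$inner))
  din <- cbind(p[1L] - section$inner[J, 1L], p[2L] - section$inner[J, 2L])
  dout <- cbind(p[1L] - section$outer[J, 1L], p[2L] - section$outer[J, 2L])
  rin <- sqrt(rowSums(din^2)); rout <- sqrt(rowSums(dout^2))
  if (min(rin, rout) < 1e-9)
    cyclo_stop("field evaluated within 1e-9 px of a charge",
               "cyclo_singularity")
  colSums(din / rin^3) - params$rigidity * colSums(dout / rout^3)
}

## scatter variance of a traced polyline: (1/K) sum_{k=0..K} |p_k - mean|^2
## with K = number of steps (rows - 1), mean = (1/K) sum p_k as in the
## incremental construction
line_variance <- function(pts) {
  K <- nrow(pts) - 1L
  if (K < 1L) return(0)
  ctr <- colSums(pts) / K
  sum((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2) / K
}

#' Trace one field line across the annulus
#'
#' Starts at inner boundary point `i`, takes the first step of length
#' `delta` along the inward boundary normal, then follows the normalized
#' windowed field (evaluated at the tip of the previous increment) in
#' steps of `delta` until the line lands on or beyond the outer boundary
#' (complete) or `k_max` steps are exhausted (stray). The scatter variance
#' test is applied to every line afterwards: variance below `v_min` marks
#' it collapsed. For complete lines the final segment is clipped at its
#' exact intersection with the outer polygon and the line length `d`
#' (local wall thickness, pixels) includes the clipped segment.
#'
#' @param section an `annulus_section`.
#' @param i inner boundary point index (1-based).
#' @param params a `field_params` object.
#' @param clip clip the final segment at the outer polygon (default
#'   `TRUE`); with `FALSE` the length quantizes to whole steps.
#' @return A `field_line`: list with `index`, `points` (k+1 x 2 matrix),
#'   `status` (`"complete"`, `"stray"` or `"collapsed"`), `length` (`d`,
#'   `NA` unless complete) and `variance`.
#' @export
trace_field_line <- function(section, i, params, clip = TRUE) {
  p0 <- section$inner[i, ]
  nrm <- inward_normal(section, i, params$delta)
  if (is.null(nrm)) {
    return(structure(list(index = i, points = matrix(p0, ncol = 2L),
                          status = "collapsed", length = NA_real_,
                          variance = 0), class = "field_line"))
  }
  pts <- matrix(NA_real_, params$k_max + 1L, 2L)
  pts[1L, ] <- p0
  pts[2L, ] <- p0 + params$delta * nrm
  k <- 2L
  status <- "stray"
  while (TRUE) {
    p <- pts[k, ]
    if (!annulus_contains(p, section) &&
        !point_in_polygon(p, section$inner, boundary = TRUE)) {
      status <- "complete"  # on or beyond the outer boundary
      break
    }
    if (k > params$k_max) break
    E <- tryCatch(electric_field(p, section, i, params),
                  cyclo_singularity = function(e) NULL)
    if (is.null(E)) break  # stalled onto a charge: leave as stray
    nE <- sqrt(sum(E^2))
    if (nE <= 0) break
    pts[k + 1L, ] <- p + params$delta * E / nE
    k <- k + 1L
  }
  pts <- pts[seq_len(k), , drop = FALSE]
  d <- NA_real_
  if (status == "complete") {
    if (clip) {
      hit <- segment_polygon_intersection(pts[k - 1L, ], pts[k, ],
                                          section$outer)
      if (!is.null(hit)) pts[k, ] <- hit$point
    }
    d <- sum(sqrt(rowSums(diff(pts)^2)))
  }
  v <- line_variance(pts)
  if (v < params$v_min) status <- "collapsed"
  structure(list(index = i, points = pts, status = status,
                 length = if (status == "complete") d else NA_real_,
                 variance = v),
            class = "field_line")
}

#' Trace field lines from every inner boundary point
#'
#' Traces all I lines of a section and returns the complete ones in
#' increasing index order; stray and collapsed lines are discarded and
#' their counts attached as attributes (`n_stray`, `n_collapsed`) and
#' reported when `verbose`.
#'
#' @inheritParams trace_field_line
#' @param verbose report removed-line counts.
#' @return List of complete `field_line`s with count attributes.
#' @export
trace_all <- function(section, params, clip = TRUE, verbose = FALSE) {
  I <- nrow(section$inner)
  if (params$n_points != I)
    cyclo_stop("params$n_points does not match the section's point count",
               "cyclo_contract_error")
  lines <- lapply(seq_len(I), trace_field_line, section = section,
                  params = params, clip = clip)
  status <- vapply(lines, `[[`, "", "status")
  keep <- lines[status == "complete"]
  n_stray <- sum(status == "stray"); n_collapsed <- sum(status == "collapsed")
  cyclo_log(verbose,
            "slice %s: %d complete, %d stray, %d collapsed field lines",
            ifelse(is.na(section$slice), "?", section$slice),
            length(keep), n_stray, n_collapsed)
  if (length(keep) < 4L)
    cyclo_stop(sprintf(
      "meshing failure: only %d complete field lines (%d stray, %d collapsed); need >= 4",
      length(keep), n_stray, n_collapsed), "cyclo_meshing_failure")
  structure(keep, n_stray = n_stray, n_collapsed = n_collapsed)
}

#' Export traced field lines as plain polyline lists
#'
#' Diagnostic helper: converts traced lines into a JSON-ready list of
#' polylines (one `list(index, status, points)` per line) for overlay QA.
#'
#' @param lines list of `field_line`s.
#' @param path optional JSON output path; when given, written with
#'   [jsonlite::write_json()].
#' @return The list, invisibly when written to `path`.
#' @export
field_lines_json <- function(lines, path = NULL) {
  out <- lapply(lines, function(ln)
    list(index = ln$index, status = ln$status,
         points = unname(ln$points)))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
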