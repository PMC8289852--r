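# End-to-end pipeline: configuration, the unroll run, cyclorama output
# with provenance sidecar, and the inverse-mapping run.

#' Unrolling run configuration
#'
#' Collects and validates every parameter of an unrolling run before any
#' computation. The defaults mirror the parameter set the method was
#' developed with (200-point contours, 31-point charge window, 2 px
#' segments, minimum variance 50, rigidity 1, interpolation interval 20).
#'
#' @param stack path to the input image stack (TIFF file or directory).
#' @param contours path to the boundary contours (`.json` or ImageJ
#'   `.zip`).
#' @param out output prefix; the run writes `<out>.tif` (C-page
#'   cyclorama), `<out>_map.rds` (coordinate sidecar) and
#'   `<out>_params.json` (provenance).
#' @param n_points,window,delta,rigidity,k_max,v_min see [field_params()].
#' @param m interpolation interval in slices.
#' @param n_levels C, number of depth levels.
#' @param origin rotation axis `(ox, oy)` or `NULL` for the centroid of
#'   the first inner contour.
#' @param interp probing interpolation, `"bilinear"` or `"nearest"`.
#' @param fill out-of-bounds fill value.
#' @param reverse reverse the cyclorama column direction.
#' @param verbose log per-slice line counts and probe statistics.
#' @return A validated `run_config` list.
#' @export
run_config <- function(stack = NULL, contours = NULL, out = NULL,
                       n_points = 200L, window = 15L, delta = 2,
                       rigidity = 1, k_max = 75L, v_min = 50, m = 20L,
                       n_levels = 30L, origin = NULL,
                       interp = "bilinear", fill = 0, reverse = FALSE,
                       verbose = FALSE) {
  fp <- field_params(n_points, window, delta, rigidity, k_max, v_min)
  if (m < 1L) cyclo_stop("m must be >= 1", "cyclo_parameter_error")
  if (n_levels < 2L)
    cyclo_stop("need at least 2 depth levels", "cyclo_parameter_error")
  if (!is.null(origin) && length(origin) != 2L)
    cyclo_stop("origin must be (ox, oy)", "cyclo_parameter_error")
  structure(list(stack = stack, contours = contours, out = out,
                 params = fp, m = as.integer(m),
                 n_levels = as.integer(n_levels), origin = origin,
                 interp = interp, fill = fill,
                 reverse = isTRUE(reverse), verbose = isTRUE(verbose)),
            class = "run_config")
}

## serializable snapshot of a run_config
config_snapshot <- function(config) {
  list(stack = config$stack, contours = config$contours,
       n_points = config$params$n_points, window = config$params$window,
       delta = config$params$delta, rigidity = config$params$rigidity,
       k_max = config$params$k_max, v_min = config$params$v_min,
       m = config$m, n_levels = config$n_levels,
       origin = config$origin, interp = config$interp,
       fill = config$fill, reverse = config$reverse)
}

#' Build re-slicing surfaces from boundary sections
#'
#' The meshing half of the pipeline: normalizes and pairs the key-slice
#' boundary contours, traces field lines on each key slice, builds the
#' internal contours at all depth levels, and interpolates them across
#' all slices with vertical natural cubic splines.
#'
#' @param sections list of raw per-slice boundary pairs
#'   (`list(slice, inner, outer)`, as from [read_contours()]).
#' @param n_slices H, total slice count of the stack.
#' @param config a `run_config`.
#' @return A `reslicing_set`; the per-key-slice complete field lines are
#'   attached as attribute `"lines"`.
#' @export
mesh_sections <- function(sections, n_slices, config) {
  keyed <- lapply(sections, function(sl) {
    inner <- normalize_contour(sl$inner, config$params$n_points)
    outer <- normalize_contour(sl$outer, config$params$n_points)
    pair_boundaries(inner, outer, slice = sl$slice)
  })
  names(keyed) <- vapply(sections, `[[`, 0L, "slice")
  lines <- lapply(keyed, function(sec)
    trace_all(sec, config$params, verbose = config$verbose))
  key_contours <- lapply(lines, internal_contours,
                         n_levels = config$n_levels,
                         n_points = config$params$n_points)
  surfaces <- interpolate_sections(key_contours, n_slices)
  attr(surfaces, "lines") <- lines
  surfaces
}

#' Run the full unrolling pipeline
#'
#' Reads the stack and boundary contours, meshes the wall with field
#' lines, interpolates the re-slicing surfaces, probes the volume into a
#' 3D cyclorama and (when `config$out` is set) writes the cyclorama
#' TIFF, the coordinate sidecar and the parameter JSON.
#'
#' @param config a `run_config` with `stack` and `contours` set.
#' @return The `cyclorama`, invisibly when written to disk.
#' @export
run_unroll <- function(config) {
  volume <- read_stack(config$stack)
  sections <- read_contours(config$contours)
  n_slices <- dim(volume)[3L]
  surfaces <- mesh_sections(sections, n_slices, config)
  cyclo <- probe_volume(volume, surfaces, origin = config$origin,
                        interp = config$interp, fill = config$fill,
                        reverse = config$reverse, verbose = config$verbose)
  cyclo$bits <- attr(volume, "bits")
  if (!is.null(config$out)) {
    write_cyclorama(cyclo, config$out, config)
    return(invisible(cyclo))
  }
  cyclo
}

#' Write a cyclorama with its sidecar
#'
#' `<out>.tif` holds one H x L page per depth level (bit depth matched to
#' the input stack); `<out>_map.rds` holds the full cyclorama object
#' including the source coordinate tables; `<out>_params.json` records
#' the run parameters, so a run is reproducible from the sidecar plus
#' the inputs.
#'
#' @param cyclo a `cyclorama`.
#' @param out output prefix.
#' @param config optional `run_config` recorded in the provenance JSON.
#' @return The output prefix, invisibly.
#' @export
write_cyclorama <- function(cyclo, out, config = NULL) {
  bits <- cyclo$bits %||% 8L
  vmax <- 2^bits - 1
  pages <- lapply(seq_len(dim(cyclo$values)[3L]), function(ci)
    pmin(pmax(t(cyclo$values[, , ci]), 0), vmax) / vmax)
  tiff::writeTIFF(pages, paste0(out, ".tif"), bits.per.sample = bits)
  saveRDS(cyclo, paste0(out, "_map.rds"))
  prov <- list(dims = dim(cyclo$values), origin = cyclo$origin,
               interp = cyclo$interp, fill = cyclo$fill,
               n_oob = cyclo$n_oob, bits = bits)
  if (!is.null(config)) prov$config <- config_snapshot(config)
  jsonlite::write_json(prov, paste0(out, "_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Inverse-map seed points from a cyclorama sidecar
#'
#' Reads seed cells from a JSON file (`[{"l":..,"h":..,"c":..}, ...]` or
#' `{"points": [[l,h,c], ...]}`, 1-based), maps them back into the voxel
#' grid via [inverse_map()], dilates each to a cube and writes the
#' resulting binary mask as a multi-page TIFF with the original stack's
#' dimensions (a seed image for region-growing segmentation).
#'
#' @param sidecar path to a `<out>_map.rds` sidecar.
#' @param points path to the seed-point JSON.
#' @param out output mask `.tif` path.
#' @param cube odd cube edge in voxels (the seed volumes; e.g. 5 for
#'   5 x 5 x 5 cubes).
#' @return The mask array, invisibly.
#' @export
run_invmap <- function(sidecar, points, out, cube = 5L) {
  cyclo <- readRDS(sidecar)
  doc <- jsonlite::fromJSON(points, simplifyVector = TRUE)
  cells <- if (is.data.frame(doc)) as.matrix(doc[, c("l", "h", "c")])
  else if (!is.null(doc$points)) matrix(unlist(doc$points), ncol = 3L,
                                        byrow = !is.matrix(doc$points))
  else cyclo_stop("unrecognised seed-point JSON", "cyclo_format_error")
  if (!is.null(doc$points) && is.matrix(doc$points)) cells <- doc$points
  mask <- inverse_map(cells, cyclo, cube = cube)
  pages <- lapply(seq_len(dim(mask)[3L]), function(h) mask[, , h] * 1)
  tiff::writeTIFF(pages, out, bits.per.sample = 8L)
  invisible(mask)
}

#' Write a phantom data set to disk
#'
#' Renders a preset phantom and writes the TIFF stack, the JSON boundary
#' contours and a ground-truth marker CSV, ready to feed [run_unroll()].
#'
#' @param preset see [phantom_preset()].
#' @param dir output directory (created if missing).
#' @param seed RNG seed recorded in the spec.
#' @param key_interval contour emission interval in slices.
#' @param ... overrides passed to [phantom_spec()].
#' @return Named list of the written paths, invisibly.
#' @export
run_phantom <- function(preset, dir, seed = 1L, key_interval = 20L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- phantom_preset(preset, seed = seed, ...)
  ph <- make_tube(spec, key_interval = key_interval)
  paths <- list(stack = file.path(dir, "stack.tif"),
                contours = file.path(dir, "contours.json"),
                markers = file.path(dir, "markers.csv"))
  write_stack(ph$volume, paths$stack, bits = ph$bits)
  write_contours_json(ph$contours, paths$contours)
  if (!is.null(ph$markers)) {
    utils::write.csv(cbind(id = seq_len(nrow(ph$markers)), ph$markers),
                     paths$markers, row.names = FALSE)
  } else {
    paths$markers <- NULL
  }
  invisible(paths)
}
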