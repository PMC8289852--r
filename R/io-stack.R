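# Grey-value image stack I/O: multi-page TIFF or a directory of
# numerically ordered single-page TIFFs.

#' Read a 3D grey-value image stack
#'
#' Accepts a multi-page TIFF file or a directory of single-page TIFFs
#' (sorted by file name). Grey values are returned unscaled (integer
#' units of the stored bit depth); slice order is page/file order.
#'
#' @param path TIFF file or directory.
#' @return Numeric array `[rows, cols, H]` with attribute `"bits"`.
#' @export
read_stack <- function(path) {
  pages <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files))
      cyclo_stop(paste("no TIFF files in", path), "cyclo_format_error")
    lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE, info = TRUE))
  } else {
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  }
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of non-grey input
    attr(p, "bits.per.sample") <- b
    p
  })
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    cyclo_stop("slices have mixed dimensions", "cyclo_format_error")
  bits <- vapply(pages, function(p)
    as.integer(attr(p, "bits.per.sample") %||% if (max(p) > 255) 16L else 8L),
    0L)
  if (length(unique(bits)) > 1L)
    cyclo_stop("slices have mixed bit depths", "cyclo_format_error")
  vol <- array(0, c(dims[1L, 1L], dims[2L, 1L], length(pages)))
  for (h in seq_along(pages)) vol[, , h] <- pages[[h]]
  attr(vol, "bits") <- bits[1L]
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 3D grey-value image stack
#'
#' Writes the volume as a multi-page TIFF, one page per slice, with
#' values stored at the given bit depth.
#'
#' @param volume numeric array `[rows, cols, H]` of integer grey values.
#' @param path output `.tif` path.
#' @param bits bit depth (8 or 16); default taken from the volume's
#'   `"bits"` attribute, falling back to 8.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, bits = NULL) {
  bits <- as.integer(bits %||% attr(volume, "bits") %||% 8L)
  if (!bits %in% c(8L, 16L))
    cyclo_stop("bits must be 8 or 16", "cyclo_parameter_error")
  vmax <- 2^bits - 1
  pages <- lapply(seq_len(dim(volume)[3L]), function(h)
    pmin(pmax(volume[, , h], 0), vmax) / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}
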