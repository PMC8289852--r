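# Boundary contour I/O.
#
# Two formats are supported:
#  * a JSON dialect:
#      {"slices": [{"h": <int>, "inner": [[x,y],...], "outer": [[x,y],...]}]}
#    (lossless, the preferred interchange format), and
#  * ImageJ ROI .zip archives of polygon/freehand ROIs. ImageJ ROI files
#    carry no role metadata, so the naming convention inner_*/outer_* is
#    required; the slice index is taken from the ROI position field.
#    Classic ROI coordinates are 16-bit integers, so the writer rounds to
#    whole pixels.

#' Read boundary contours
#'
#' Dispatches on the file extension: `.json` for the JSON contour
#' dialect, `.zip` for ImageJ ROI archives.
#'
#' @param path contour file.
#' @return List of per-slice boundary pairs, each
#'   `list(slice, inner, outer)` with n x 2 coordinate matrices, sorted
#'   by slice; raw coordinates, not yet normalized or paired.
#' @export
read_contours <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_contours_json(path)
  else if (grepl("\\.zip$", path, ignore.case = TRUE)) read_roi_zip(path)
  else cyclo_stop("unrecognised contour format (expect .json or .zip)",
                  "cyclo_format_error")
}

#' @rdname read_contours
#' @export
read_contours_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$slices))
    cyclo_stop("contour JSON lacks a 'slices' array", "cyclo_format_error")
  out <- lapply(doc$slices, function(sl) {
    if (is.null(sl$h) || is.null(sl$inner) || is.null(sl$outer))
      cyclo_stop("each slice needs 'h', 'inner' and 'outer'",
                 "cyclo_format_error")
    as_mat <- function(p) do.call(rbind, lapply(p, function(q)
      c(as.numeric(q[[1L]]), as.numeric(q[[2L]]))))
    list(slice = as.integer(sl$h), inner = as_mat(sl$inner),
         outer = as_mat(sl$outer))
  })
  out[order(vapply(out, `[[`, 0L, "slice"))]
}

#' Write boundary contours as JSON
#'
#' @param sections list of `list(slice, inner, outer)` entries (as
#'   returned by [read_contours()] or [make_tube()]'s `contours`).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_contours_json <- function(sections, path) {
  doc <- list(slices = lapply(sections, function(sl)
    list(h = sl$slice, inner = unname(as_xy(sl$inner)),
         outer = unname(as_xy(sl$outer)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- ImageJ ROI binary format (classic, polygon type) ----------------
## Byte layout per ImageJ's RoiDecoder: "Iout", version (short), type
## (byte), bounding box (4 shorts), n (short), ..., position (int, byte
## 56), header2 offset (int, byte 60), then n x-shorts and n y-shorts
## relative to (left, top).

encode_roi <- function(xy, position) {
  xy <- round(as_xy(xy))
  left <- min(xy[, 1L]); top <- min(xy[, 2L])
  right <- max(xy[, 1L]); bottom <- max(xy[, 2L])
  n <- nrow(xy)
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  writeChar("Iout", con, 4L, eos = NULL)
  writeBin(c(228L, 0L), con, size = 1L)            # version 228
  writeBin(0L, con, size = 1L)                      # type 0 = polygon
  writeBin(0L, con, size = 1L)                      # pad
  writeBin(as.integer(c(top, left, bottom, right, n)), con, size = 2L,
           endian = "big")
  writeBin(raw(56L - 18L), con)                     # unused header fields
  seek(con, 56L)
  writeBin(as.integer(position), con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big")      # no header2
  writeBin(as.integer(c(xy[, 1L] - left, xy[, 2L] - top)), con, size = 2L,
           endian = "big")
  rawConnectionValue(con)
}

decode_roi <- function(bytes) {
  if (length(bytes) < 64L || rawToChar(bytes[1:4]) != "Iout")
    cyclo_stop("not an ImageJ ROI file", "cyclo_format_error")
  type <- as.integer(bytes[7L])
  if (!type %in% c(0L, 7L))  # polygon or freehand
    cyclo_stop(sprintf("unsupported ROI type %d (need polygon/freehand)",
                       type), "cyclo_format_error")
  rd2 <- function(off) readBin(bytes[(off + 1L):(off + 2L)], "integer",
                               size = 2L, endian = "big")
  rd4 <- function(off) readBin(bytes[(off + 1L):(off + 4L)], "integer",
                               size = 4L, endian = "big")
  top <- rd2(8L); left <- rd2(10L); n <- rd2(16L)
  position <- rd4(56L)
  coords <- readBin(bytes[65:(64L + 4L * n)], "integer", n = 2L * n,
                    size = 2L, endian = "big")
  list(xy = cbind(coords[seq_len(n)] + left, coords[n + seq_len(n)] + top),
       position = position)
}

## Minimal STORED (uncompressed) zip writer: local file headers + central
## directory, CRC-32 computed in R. Readable by utils::unzip and ImageJ.
## 32-bit unsigned xor on doubles (values in [0, 2^32))
bitwXor64 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

crc32 <- function(bytes) {
  crc <- 4294967295  # doubles keep the 32 unsigned bits exactly
  for (b in as.integer(bytes)) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    crc <- bitwXor64(crc %/% 256, crc32_lookup[idx + 1L])
  }
  bitwXor64(crc, 4294967295)
}

## precomputed unsigned CRC-32 table (poly 0xEDB88320)
crc32_lookup <- local({
  t <- numeric(256L)
  for (i in 0:255) {
    crc <- i
    for (j in 1:8) {
      odd <- crc %% 2
      crc <- (crc - odd) / 2
      if (odd) crc <- bitwXor64(crc, 3988292384)  # 0xEDB88320
    }
    t[i + 1L] <- crc
  }
  t
})

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) {
  b <- numeric(4L)
  for (i in 1:4) { b[i] <- x %% 256; x <- (x - b[i]) / 256 }
  as.raw(b)
}

write_stored_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  pos <- 0
  central <- raw(0L)
  for (k in seq_along(entries)) {
    name <- charToRaw(names(entries)[k])
    data <- entries[[k]]
    crc <- crc32(data)
    offsets[k] <- pos
    local_hdr <- c(u32(67324752),            # PK\3\4
                   u16(20), u16(0), u16(0),  # version, flags, method=stored
                   u16(0), u16(0),           # time, date
                   u32(crc), u32(length(data)), u32(length(data)),
                   u16(length(name)), u16(0), name)
    writeBin(local_hdr, con)
    writeBin(data, con)
    pos <- pos + length(local_hdr) + length(data)
    central <- c(central,
                 u32(33639248),              # PK\1\2
                 u16(20), u16(20), u16(0), u16(0),
                 u16(0), u16(0),
                 u32(crc), u32(length(data)), u32(length(data)),
                 u16(length(name)), u16(0), u16(0),
                 u16(0), u16(0), u32(0), u32(offsets[k]), name)
  }
  writeBin(central, con)
  writeBin(c(u32(101010256),                 # PK\5\6
             u16(0), u16(0),
             u16(length(entries)), u16(length(entries)),
             u32(length(central)), u32(pos), u16(0)), con)
  invisible(path)
}

#' Write boundary contours as an ImageJ ROI zip archive
#'
#' One polygon ROI per boundary, named `inner_<slice>.roi` /
#' `outer_<slice>.roi` with the slice index stored in the ROI position
#' field. Coordinates are rounded to integer pixels (classic ROI format).
#'
#' @inheritParams write_contours_json
#' @param path output `.zip` path.
#' @return `path`, invisibly.
#' @export
write_roi_zip <- function(sections, path) {
  entries <- list()
  for (sl in sections) {
    entries[[sprintf("inner_%04d.roi", sl$slice)]] <-
      encode_roi(sl$inner, sl$slice)
    entries[[sprintf("outer_%04d.roi", sl$slice)]] <-
      encode_roi(sl$outer, sl$slice)
  }
  write_stored_zip(entries, path)
}

#' @rdname read_contours
#' @export
read_roi_zip <- function(path) {
  tmp <- tempfile("roizip")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- utils::unzip(path, exdir = tmp)
  rois <- lapply(files, function(f)
    c(decode_roi(readBin(f, raw(), file.size(f))),
      list(name = tolower(basename(f)))))
  role <- ifelse(grepl("^inner", vapply(rois, `[[`, "", "name")), "inner",
                 ifelse(grepl("^outer", vapply(rois, `[[`, "", "name")),
                        "outer", NA))
  if (anyNA(role))
    cyclo_stop("ROI names must start with inner_ or outer_",
               "cyclo_format_error")
  slices <- vapply(rois, `[[`, 0L, "position")
  out <- lapply(sort(unique(slices)), function(h) {
    ii <- which(slices == h & role == "inner")
    oo <- which(slices == h & role == "outer")
    if (length(ii) != 1L || length(oo) != 1L)
      cyclo_stop(sprintf("slice %d needs exactly one inner and one outer ROI", h),
                 "cyclo_format_error")
    list(slice = as.integer(h), inner = rois[[ii]]$xy, outer = rois[[oo]]$xy)
  })
  out
}
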