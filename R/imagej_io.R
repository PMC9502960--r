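# ImageJ .roi binary format (big-endian, 64-byte header starting "Iout").
# Single-ring ROIs are written as polygon records; multi-ring ROIs as shape
# (composite) records holding a MOVETO/LINETO/CLOSE float segment array, which
# is how ImageJ serializes composite selections. Non-integer vertices use the
# sub-pixel option (bit 128): float coordinates appended after the integer
# ones. Unknown header options are ignored on read.

IJ_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
              polyline = 5L, noRoi = 6L, freehand = 7L, traced = 8L,
              angle = 9L, point = 10L)
IJ_OPT_SUBPIXEL <- 128L

#' Read an ImageJ .roi file
#'
#' Supports polygon, freehand, traced, rectangle, oval, and composite (shape)
#' records, with or without sub-pixel coordinates. Oval selections are
#' approximated by a 72-gon inscribed in the stored bounding box. The label
#' and grader of the returned [roi] are left unset for the caller to assign.
#'
#' @param con a file path or raw vector.
#' @return a [roi].
#' @export
read_imagej_roi <- function(con) {
  bytes <- if (is.raw(con)) con else readBin(con, "raw", file.size(con))
  if (length(bytes) < 64 || rawToChar(bytes[1:4]) != "Iout")
    oc_stop("format_error", "not an ImageJ ROI stream (magic 'Iout' missing)")
  u16 <- function(off) readBin(bytes[off + 1:2], "integer", size = 2,
                               endian = "big", signed = FALSE)
  s16 <- function(off) readBin(bytes[off + 1:2], "integer", size = 2,
                               endian = "big", signed = TRUE)
  i32 <- function(off) readBin(bytes[off + 1:4], "integer", size = 4,
                               endian = "big")
  f32 <- function(off, n) readBin(bytes[off + 1:(4 * n)], "double", n = n,
                                  size = 4, endian = "big")
  type <- as.integer(bytes[7])
  top <- s16(8); left <- s16(10); bottom <- s16(12); right <- s16(14)
  n <- u16(16)
  shape_size <- i32(36)
  options <- u16(50)

  if (type == IJ_TYPES["rect"] && shape_size > 0) {
    seg <- f32(64, shape_size)
    rings <- list(); cur_x <- numeric(); cur_y <- numeric(); k <- 1
    flush <- function() {
      if (length(cur_x) >= 3)
        rings[[length(rings) + 1]] <<- list(x = cur_x, y = cur_y)
      cur_x <<- numeric(); cur_y <<- numeric()
    }
    while (k <= length(seg)) {
      op <- seg[k]
      if (op == 0) {            # MOVETO
        flush(); cur_x <- seg[k + 1]; cur_y <- seg[k + 2]; k <- k + 3
      } else if (op == 1) {     # LINETO
        cur_x <- c(cur_x, seg[k + 1]); cur_y <- c(cur_y, seg[k + 2])
        k <- k + 3
      } else if (op == 4) {     # CLOSE
        flush(); k <- k + 1
      } else {
        oc_stop("unsupported_type_error",
                "shape ROI contains curved segment (op %d), not supported",
                op)
      }
    }
    flush()
    if (!length(rings))
      oc_stop("format_error", "shape ROI decodes to no rings")
    return(roi(rings))
  }

  if (type == IJ_TYPES["rect"]) {
    return(roi(list(x = c(left, right, right, left),
                    y = c(top, top, bottom, bottom))))
  }
  if (type == IJ_TYPES["oval"]) {
    cx <- (left + right) / 2; cy <- (top + bottom) / 2
    rx <- (right - left) / 2; ry <- (bottom - top) / 2
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    return(roi(list(x = cx + rx * cos(th), y = cy + ry * sin(th))))
  }
  if (type %in% IJ_TYPES[c("polygon", "freehand", "traced")]) {
    if (n < 3) oc_stop("format_error", "polygon ROI with < 3 vertices")
    xi <- vapply(seq_len(n), function(i) s16(64 + 2 * (i - 1)), 0L) + left
    yi <- vapply(seq_len(n), function(i) s16(64 + 2 * n + 2 * (i - 1)), 0L) +
      top
    subpixel <- bitwAnd(options, IJ_OPT_SUBPIXEL) != 0 &&
      length(bytes) >= 64 + 4 * n + 8 * n
    if (subpixel) {
      xf <- f32(64 + 4 * n, n)
      yf <- f32(64 + 4 * n + 4 * n, n)
      return(roi(list(x = xf, y = yf)))
    }
    return(roi(list(x = as.numeric(xi), y = as.numeric(yi))))
  }
  name <- names(IJ_TYPES)[match(type, IJ_TYPES)]
  oc_stop("unsupported_type_error", "unsupported ImageJ ROI type: %s",
          if (is.na(name)) as.character(type) else name)
}

#' Write a [roi] as ImageJ .roi bytes
#'
#' Round-trip guarantee: `read_imagej_roi(write_imagej_roi(r))` reproduces
#' the rings exactly for integer vertices and to 32-bit float precision
#' otherwise.
#'
#' @param roi a valid [roi].
#' @param path optional file path; when `NULL` the raw vector is returned.
#' @return raw vector (invisibly when `path` given).
#' @export
write_imagej_roi <- function(roi, path = NULL) {
  stopifnot(inherits(roi, "roi"))
  if (length(roi$rings) < 1)
    oc_stop("invalid_roi_error", "cannot write an ROI with no rings")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  w8 <- function(x) writeBin(as.integer(x), con, size = 1)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  wf32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "big")

  xs <- unlist(lapply(roi$rings, `[[`, "x"))
  ys <- unlist(lapply(roi$rings, `[[`, "y"))
  bb <- c(floor(min(ys)), floor(min(xs)),
          ceiling(max(ys)) + 1, ceiling(max(xs)) + 1)  # top left bottom right
  composite <- length(roi$rings) > 1

  writeChar("Iout", con, 4, eos = NULL)
  w16(228)                                   # version
  w8(if (composite) IJ_TYPES["rect"] else IJ_TYPES["polygon"]); w8(0)
  w16(bb)                                    # top, left, bottom, right
  if (composite) {
    seg <- unlist(lapply(roi$rings, function(r) {
      n <- length(r$x)
      c(0, r$x[1], r$y[1],
        as.vector(rbind(1, r$x[-1], r$y[-1])), 4)
    }))
    w16(0)                                   # nCoordinates
    wf32(rep(0, 4))                          # x1 y1 x2 y2
    w16(0)                                   # stroke width
    w32(length(seg))                         # shapeRoiSize
    w32(c(0L, 0L))                           # stroke/fill color
    w16(c(0L, 0L))                           # subtype, options
    w8(c(0L, 0L)); w16(0L)                   # arrow fields, arc size
    w32(0L); w32(0L)                         # position, header2
    wf32(seg)
  } else {
    ring <- roi$rings[[1]]
    n <- length(ring$x)
    subpixel <- any(ring$x != round(ring$x)) || any(ring$y != round(ring$y))
    w16(n)
    wf32(rep(0, 4))
    w16(0)
    w32(0L)
    w32(c(0L, 0L))
    w16(0L)                                  # subtype
    w16(if (subpixel) IJ_OPT_SUBPIXEL else 0L)
    w8(c(0L, 0L)); w16(0L)
    w32(0L); w32(0L)
    w16(round(ring$x) - bb[2])               # x relative to left
    w16(round(ring$y) - bb[1])               # y relative to top
    if (subpixel) { wf32(ring$x); wf32(ring$y) }
  }
  bytes <- rawConnectionValue(con)
  if (!is.null(path)) {
    writeBin(bytes, path)
    return(invisible(bytes))
  }
  bytes
}

#' Read all .roi entries from a .zip bundle
#'
#' @param path a .zip archive of .roi files.
#' @return named list of [roi] in archive order.
#' @export
read_roi_zip <- function(path) {
  if (!file.exists(path))
    oc_stop("format_error", "ROI bundle not found: %s", path)
  entries <- unzip(path, list = TRUE)$Name
  entries <- entries[grepl("\\.roi$", entries, ignore.case = TRUE)]
  exdir <- tempfile("roizip")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  unzip(path, files = entries, exdir = exdir)
  out <- lapply(entries, function(e) read_imagej_roi(file.path(exdir, e)))
  names(out) <- sub("\\.roi$", "", basename(entries), ignore.case = TRUE)
  out
}

#' Write a list of ROIs as a .zip bundle of .roi entries
#'
#' Writes a stored (uncompressed) ZIP archive directly, so no external `zip`
#' program is needed.
#'
#' @param rois named list of [roi]; names become entry names.
#' @param path output .zip path.
#' @return `path`, invisibly.
#' @export
write_roi_zip <- function(rois, path) {
  if (!length(rois)) oc_stop("empty_input_error", "no ROIs to write")
  nm <- names(rois) %||% sprintf("roi%03d", seq_along(rois))
  nm[nm == ""] <- sprintf("roi%03d", which(nm == ""))
  payloads <- lapply(rois, write_imagej_roi)
  write_stored_zip(setNames(payloads, paste0(nm, ".roi")), path)
  invisible(path)
}

# ---- minimal stored ZIP writer ------------------------------------------

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1), -306674912L)  # 0xEDB88320
      else bitwShiftR(c, 1)
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (v in b)
    crc <- bitwXor(bitwShiftR(crc, 8),
                   crc32_table[bitwAnd(bitwXor(crc, v), 255L) + 1L])
  bitwXor(crc, -1L)
}

write_stored_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    w32(67324752L)                 # local file header signature
    w16(c(20L, 0L, 0L, 0L, 33L))   # version, flags, method, time, date
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(c(length(name), 0L))
    writeBin(name, con); writeBin(data, con)
    pos <- pos + 30L + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    w32(33639248L)                 # central directory signature
    w16(c(20L, 20L, 0L, 0L, 0L, 33L))
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(c(length(name), 0L, 0L, 0L, 0L))
    w32(0L)                        # external attributes
    w32(offsets[i])
    writeBin(name, con)
    pos <- pos + 46L + length(name)
  }
  w32(101010256L)                  # end of central directory
  w16(c(0L, 0L, length(entries), length(entries)))
  w32(pos - cd_start); w32(cd_start)
  w16(0L)
  invisible(path)
}
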