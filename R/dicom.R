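# Minimal multi-frame DICOM support.
#
# Scope: part-10 files (128-byte preamble + "DICM"), explicit or implicit VR
# little endian, uncompressed pixel data, 8- or 16-bit grayscale. This covers
# what the measurement pipeline needs (PixelSpacing, Rows, Columns,
# NumberOfFrames, BitsAllocated, PixelData); everything else is skipped by
# length. Encapsulated/compressed transfer syntaxes raise a classed error.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

read_dicom_multiframe <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    fb_stop("fb_format_error", "not a part-10 DICOM file: %s", path)
  pos <- 133L
  ts <- TS_EXPLICIT_LE
  elems <- list()
  repeat {
    if (pos + 7L > length(raw)) break
    group <- u16(raw, pos)
    explicit <- group == 0x0002 || ts == TS_EXPLICIT_LE
    el <- parse_element(raw, pos, explicit)
    if (is.null(el)) break
    key <- sprintf("%04x,%04x", el$group, el$element)
    elems[[key]] <- el
    if (key == "0002,0010") ts <- dicom_string(el)
    pos <- el$next_pos
    if (key == "7fe0,0010") break
  }
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
    fb_stop("fb_unsupported_format",
            "unsupported DICOM transfer syntax %s (only uncompressed %s)",
            ts, "little-endian is readable)")
  need <- function(key, what) {
    if (is.null(elems[[key]]))
      fb_stop("fb_format_error", "DICOM file lacks %s (%s)", what, key)
    elems[[key]]
  }
  rows <- u16(need("0028,0010", "Rows")$value, 1L)
  cols <- u16(need("0028,0011", "Columns")$value, 1L)
  bits <- if (!is.null(elems[["0028,0100"]]))
    u16(elems[["0028,0100"]]$value, 1L) else 8L
  nframes <- if (!is.null(elems[["0028,0008"]]))
    as.integer(trimws(dicom_string(elems[["0028,0008"]]))) else 1L
  spacing_cm <- NULL
  if (!is.null(elems[["0028,0030"]])) {
    # PixelSpacing is row\col in mm (DICOM PS3.3); internal unit is cm
    parts <- as.numeric(strsplit(dicom_string(elems[["0028,0030"]]),
                                 "\\\\")[[1]])
    if (length(parts) == 2 && all(is.finite(parts)))
      spacing_cm <- parts / 10
  }
  pix <- need("7fe0,0010", "PixelData")$value
  bpp <- bits / 8L
  frame_bytes <- rows * cols * bpp
  if (length(pix) < nframes * frame_bytes)
    fb_stop("fb_unreadable_frame",
            "PixelData too short: have %d bytes, need %d for %d frame(s)",
            length(pix), nframes * frame_bytes, nframes)
  frames <- vector("list", nframes)
  for (i in seq_len(nframes)) {
    chunk <- pix[((i - 1L) * frame_bytes + 1L):(i * frame_bytes)]
    vals <- if (bpp == 1L) as.integer(chunk)
            else readBin(chunk, "integer", n = rows * cols, size = 2L,
                         signed = FALSE, endian = "little")
    # DICOM pixel data is row-major
    frames[[i]] <- matrix(vals, nrow = rows, byrow = TRUE)
  }
  list(frames = frames, pixel_spacing_cm = spacing_cm, bits = bits,
       transfer_syntax = ts)
}

parse_element <- function(raw, pos, explicit) {
  if (pos + 7L > length(raw)) return(NULL)
  group <- u16(raw, pos); element <- u16(raw, pos + 2L)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(raw, pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- u16(raw, pos + 6L)
      val_at <- pos + 8L
    }
  } else {
    vr <- NA_character_
    len <- u32(raw, pos + 4L)
    val_at <- pos + 8L
  }
  if (len == 0xFFFFFFFF)
    fb_stop("fb_unsupported_format",
            "undefined-length (encapsulated) DICOM elements are not supported")
  if (val_at + len - 1L > length(raw))
    fb_stop("fb_format_error", "truncated DICOM element at offset %d", pos)
  value <- if (len > 0) raw[val_at:(val_at + len - 1L)] else raw(0)
  list(group = group, element = element, vr = vr, value = value,
       next_pos = val_at + len)
}

dicom_string <- function(el) trimws(rawToChar(el$value))

u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
u32 <- function(raw, pos) {
  as.integer(raw[pos]) + 256 * as.integer(raw[pos + 1L]) +
    65536 * as.integer(raw[pos + 2L]) + 16777216 * as.integer(raw[pos + 3L])
}

#' Write a cine-loop as a minimal multi-frame DICOM file
#'
#' Produces an uncompressed explicit-VR little-endian part-10 file carrying
#' Rows/Columns/NumberOfFrames/BitsAllocated/PixelSpacing and 8-bit pixel
#' data. Intended for phantom export and round-trip testing, not for PACS
#' interchange.
#'
#' @param loop a [cineloop()]; intensities are clamped to 0..255.
#' @param path destination file.
#' @export
write_dicom <- function(loop, path) {
  stopifnot(inherits(loop, "cineloop"))
  f1 <- loop$frames[[1]]
  rows <- nrow(f1$pixels); cols <- ncol(f1$pixels)
  nfr <- length(loop$frames)
  spacing_mm <- sprintf("%.6g\\%.6g", f1$row_spacing_cm * 10,
                        f1$col_spacing_cm * 10)
  pix <- unlist(lapply(loop$frames, function(f) {
    v <- pmin(pmax(round(f$pixels), 0), 255)
    as.raw(as.integer(t(v)))  # row-major
  }))
  if (length(pix) %% 2L == 1L) pix <- c(pix, as.raw(0))

  el_short <- function(group, element, vr, value_raw) {
    if (length(value_raw) %% 2L == 1L) value_raw <- c(value_raw, as.raw(0x20))
    c(w16(group), w16(element), charToRaw(vr), w16(length(value_raw)),
      value_raw)
  }
  el_long <- function(group, element, vr, value_raw) {
    c(w16(group), w16(element), charToRaw(vr), as.raw(c(0, 0)),
      w32(length(value_raw)), value_raw)
  }
  str_raw <- function(s) charToRaw(s)

  ts_el <- el_short(0x0002, 0x0010, "UI", str_raw(TS_EXPLICIT_LE))
  meta_body <- ts_el
  meta <- c(el_short(0x0002, 0x0000, "UL", w32(length(meta_body))), meta_body)
  ds <- c(
    el_short(0x0028, 0x0002, "US", w16(1L)),
    el_short(0x0028, 0x0008, "IS", str_raw(as.character(nfr))),
    el_short(0x0028, 0x0010, "US", w16(rows)),
    el_short(0x0028, 0x0011, "US", w16(cols)),
    el_short(0x0028, 0x0030, "DS", str_raw(spacing_mm)),
    el_short(0x0028, 0x0100, "US", w16(8L)),
    el_long(0x7FE0, 0x0010, "OB", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

w16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}
w32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
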