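#' Ultrasound frame
#'
#' One grayscale frame of a cine-loop together with its physical pixel
#' spacing. All lengths in this package are carried in centimeters; any
#' mm-sourced metadata (e.g. the DICOM PixelSpacing tag) is converted exactly
#' once, at ingest.
#'
#' @param index 0-based ordinal of the frame within its loop.
#' @param pixels numeric matrix of intensities (rows x cols), at least 16x16.
#' @param row_spacing_cm,col_spacing_cm physical size of one pixel in cm;
#'   must lie strictly between 0 and 1.
#' @return An object of class `"us_frame"`.
#' @export
us_frame <- function(index, pixels, row_spacing_cm, col_spacing_cm = row_spacing_cm) {
  check_number(index, "index", lower = 0)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    fb_stop("fb_format_error", "`pixels` must be a numeric matrix")
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    fb_stop("fb_format_error", "frame must be at least 16x16, got %dx%d",
            nrow(pixels), ncol(pixels))
  check_number(row_spacing_cm, "row_spacing_cm", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  check_number(col_spacing_cm, "col_spacing_cm", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  structure(list(index = as.integer(index), pixels = pixels,
                 row_spacing_cm = row_spacing_cm,
                 col_spacing_cm = col_spacing_cm),
            class = "us_frame")
}

#' Cine-loop container
#'
#' An ordered sweep of frames of one acquisition kind. The four kinds mirror
#' the standard free-hand acquisition protocol: an axial cephalic sweep, an
#' axial abdominal sweep, a femoral sweep, and an amniotic sweep through the
#' fluid pockets.
#'
#' @param frames list of [us_frame()] objects with strictly increasing
#'   indices, identical dimensions and identical spacings.
#' @param kind one of `"cephalic"`, `"abdominal"`, `"femoral"`, `"amniotic"`.
#' @param source_id opaque provenance string.
#' @return An object of class `"cineloop"`.
#' @export
cineloop <- function(frames, kind, source_id = "unknown") {
  kind <- match.arg(kind, LOOP_KINDS)
  if (!is.list(frames) || length(frames) < 1L)
    fb_stop("fb_format_error", "a cine-loop needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "us_frame")))
    fb_stop("fb_format_error", "all frames must be us_frame objects")
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    fb_stop("fb_format_error",
            "frames with mismatched dimensions are rejected, not resized")
  sp <- vapply(frames, function(f) c(f$row_spacing_cm, f$col_spacing_cm),
               numeric(2))
  if (any(abs(sp - sp[, 1]) > 1e-12))
    fb_stop("fb_format_error", "all frames in a loop must share pixel spacing")
  idx <- vapply(frames, function(f) f$index, integer(1))
  if (any(diff(idx) <= 0))
    fb_stop("fb_format_error", "frame indices must be strictly increasing")
  structure(list(frames = frames, kind = kind,
                 source_id = as.character(source_id)),
            class = "cineloop")
}

#' @export
print.cineloop <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<cineloop> %s, %d frame(s) of %dx%d px, spacing %.4g x %.4g cm/px [%s]\n",
              x$kind, length(x$frames), d[1], d[2],
              x$frames[[1]]$row_spacing_cm, x$frames[[1]]$col_spacing_cm,
              x$source_id))
  invisible(x)
}

#' Binary label mask
#'
#' Occupancy grid for one anatomical structure on one frame. Empty masks are
#' representable; operations that require a nonempty structure say so.
#'
#' @param grid logical (or 0/1 numeric) matrix matching the parent frame.
#' @param label one of `"brain"`, `"abdomen"`, `"femur"`, `"af_pocket"`.
#' @return An object of class `"label_mask"`.
#' @export
label_mask <- function(grid, label) {
  label <- match.arg(label, MASK_LABELS)
  if (!is.matrix(grid))
    fb_stop("fb_format_error", "`grid` must be a matrix")
  if (is.numeric(grid)) grid <- grid != 0
  if (!is.logical(grid))
    fb_stop("fb_format_error", "`grid` must be logical or numeric")
  grid[is.na(grid)] <- FALSE
  structure(list(grid = grid, label = label), class = "label_mask")
}

#' Read a cine-loop from disk
#'
#' Two source layouts are supported: a multi-frame DICOM file (uncompressed
#' little-endian transfer syntaxes; pixel spacing from tag (0028,0030),
#' which DICOM states in mm and which is converted to cm here) and a
#' directory of ordered PNG frames accompanied by a flat key-value sidecar
#' `loop_meta.txt` with keys `kind`, `row_spacing_cm`, `col_spacing_cm` and
#' optionally `frame_glob` (default `*.png`). Color frames are reduced to
#' grayscale by luma.
#'
#' @param path DICOM file or frame directory.
#' @param kind loop kind; overrides any sidecar value when given.
#' @param default_spacing_cm fallback spacing when the source has none;
#'   `NULL` (default) raises a missing-spacing error instead.
#' @return A [cineloop()].
#' @export
read_cineloop <- function(path, kind = NULL, default_spacing_cm = NULL) {
  if (!file.exists(path))
    fb_stop("fb_io_error", "no such file or directory: %s", path)
  if (dir.exists(path)) {
    return(read_cineloop_dir(path, kind, default_spacing_cm))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mp4", "avi", "mov", "mkv"))
    fb_stop("fb_unsupported_format",
            "video containers are not supported by this reader; %s",
            "export the loop as multi-frame DICOM or a PNG frame directory")
  dcm <- read_dicom_multiframe(path)
  spacing <- dcm$pixel_spacing_cm
  if (is.null(spacing)) {
    if (is.null(default_spacing_cm))
      fb_stop("fb_missing_spacing",
              "no PixelSpacing tag in %s and no default spacing configured",
              path)
    spacing <- c(default_spacing_cm, default_spacing_cm)
  }
  if (is.null(kind))
    fb_stop("fb_domain_error", "`kind` is required for DICOM sources")
  frames <- lapply(seq_along(dcm$frames), function(i) {
    us_frame(i - 1L, dcm$frames[[i]], spacing[1], spacing[2])
  })
  cineloop(frames, kind, source_id = basename(path))
}

read_cineloop_dir <- function(path, kind, default_spacing_cm) {
  meta_path <- file.path(path, "loop_meta.txt")
  meta <- if (file.exists(meta_path)) read_sidecar(meta_path) else list()
  if (is.null(kind)) kind <- meta$kind
  if (is.null(kind))
    fb_stop("fb_domain_error", "loop kind not given and absent from sidecar")
  rs <- as.numeric(meta$row_spacing_cm %||% default_spacing_cm)
  cs <- as.numeric(meta$col_spacing_cm %||% rs)
  if (length(rs) == 0 || is.na(rs))
    fb_stop("fb_missing_spacing",
            "no pixel spacing in sidecar and no default configured for %s", path)
  glob <- meta$frame_glob %||% "*.png"
  files <- sort(Sys.glob(file.path(path, glob)))
  if (length(files) == 0)
    fb_stop("fb_io_error", "no frames matching '%s' under %s", glob, path)
  frames <- lapply(seq_along(files), function(i) {
    px <- tryCatch(png::readPNG(files[i]), error = function(e)
      fb_stop("fb_unreadable_frame", "frame %d (%s) unreadable: %s",
              i - 1L, basename(files[i]), conditionMessage(e)))
    us_frame(i - 1L, to_gray(px), rs, cs)
  })
  cineloop(frames, kind, source_id = basename(path))
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*[:=]\\s*(.*)$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  out
}

# luma reduction; masks and measurements are intensity-agnostic so the exact
# weights only matter for display
to_gray <- function(px) {
  if (is.matrix(px)) return(px)
  if (length(dim(px)) == 3) {
    ch <- dim(px)[3]
    if (ch >= 3)
      return(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
    return(px[, , 1])
  }
  fb_stop("fb_format_error", "unsupported pixel array layout")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a label mask
#'
#' Accepts a single-channel PNG (0 = background, nonzero = structure) or the
#' package's plain-text run-length format (`.rle`, see [write_mask()]).
#' Multi-channel PNGs are accepted only when all channels agree.
#'
#' @param path file to read.
#' @param label anatomical class of the mask.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, label) {
  if (!file.exists(path)) fb_stop("fb_io_error", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rle") return(read_mask_rle(path, label))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    ch <- dim(px)[3]
    base <- px[, , 1]
    for (k in seq_len(min(ch, 3))[-1])
      if (any(px[, , k] != base))
        fb_stop("fb_format_error",
                "multi-channel mask with disagreeing channels: %s", path)
    px <- base
  }
  label_mask(px != 0, label)
}

#' Write a label mask
#'
#' `.png` writes an 8-bit grayscale image; `.rle` writes a plain-text
#' run-length encoding (column-major 1-based runs) that round-trips exactly
#' through [read_mask()].
#'
#' @param mask a [label_mask()].
#' @param path destination; the extension selects the format.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(matrix(as.numeric(mask$grid), nrow(mask$grid)), path)
  } else if (ext == "rle") {
    v <- as.vector(mask$grid)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("fb-rle v1",
                 sprintf("rows %d", nrow(mask$grid)),
                 sprintf("cols %d", ncol(mask$grid)),
                 sprintf("label %s", mask$label),
                 sprintf("%d %d", starts[keep], r$lengths[keep])), con)
  } else {
    fb_stop("fb_unsupported_format", "unknown mask format '.%s'", ext)
  }
  invisible(path)
}

read_mask_rle <- function(path, label = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4 || lines[1] != "fb-rle v1")
    fb_stop("fb_format_error", "not an fb-rle file: %s", path)
  hdr <- function(key) {
    ln <- grep(paste0("^", key, " "), lines[2:4], value = TRUE)
    sub(paste0("^", key, " "), "", ln[1])
  }
  nr <- as.integer(hdr("rows")); nc <- as.integer(hdr("cols"))
  lab <- label %||% hdr("label")
  grid <- matrix(FALSE, nr, nc)
  runs <- lines[-(1:4)]
  runs <- runs[nzchar(runs)]
  for (rn in runs) {
    p <- as.integer(strsplit(rn, " ", fixed = TRUE)[[1]])
    grid[p[1]:(p[1] + p[2] - 1L)] <- TRUE
  }
  label_mask(grid, lab)
}
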