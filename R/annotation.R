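# Reconstruction of retrospective ground truth from burned-in overlays:
# colored caliper glyphs, dotted measurement ellipses, and the measurement
# text printed on the image (an external OCR engine turns pixels into text
# lines; only the string-level parsing lives here).

#' Caliper mark
#'
#' @param position numeric (row, col) of the mark center.
#' @param color name of the matched palette color.
#' @param glyph `"cross"` or `"x"`.
#' @return Object of class `"caliper_mark"`.
#' @export
caliper_mark <- function(position, color = "yellow",
                         glyph = c("cross", "x")) {
  glyph <- match.arg(glyph)
  structure(list(position = c(row = position[1], col = position[2]),
                 color = color, glyph = glyph),
            class = "caliper_mark")
}

#' Detect burned-in caliper marks
#'
#' Finds connected components of palette-matched pixels and keeps those
#' whose shape correlates with a cross or x template (normalized
#' cross-correlation above `ncc_threshold`); each surviving component
#' becomes a mark at its centroid. Solid palette-colored regions (e.g. a
#' colored rectangle) have zero shape variance within their bounding box and
#' are rejected by the template gate. Grayscale input yields an empty list.
#'
#' @param image RGB array (rows x cols x 3), values in `[0, 1]` or 0-255.
#' @param palette an [fb_palette()], or a subset of its colors.
#' @param ncc_threshold correlation gate.
#' @return List of [caliper_mark()] (possibly empty).
#' @export
detect_calipers <- function(image, palette = fb_palette(),
                            ncc_threshold = 0.6) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) return(list())
  img <- normalize_rgb(image)
  marks <- list()
  for (cname in names(palette$colors)) {
    hit <- palette_match(img, palette$colors[[cname]], palette$tolerance)
    if (!any(hit)) next
    lab <- label_components8(hit)
    for (k in seq_len(max(lab))) {
      pix <- which(lab == k, arr.ind = TRUE)
      if (nrow(pix) < 5) next
      ctr <- colMeans(pix)
      gl <- glyph_match(hit, ctr, ncc_threshold)
      if (is.null(gl)) next
      marks[[length(marks) + 1L]] <- caliper_mark(ctr, color = cname,
                                                  glyph = gl)
    }
  }
  marks
}

normalize_rgb <- function(image) {
  if (max(image) > 1) image / 255 else image
}

palette_match <- function(img, color, tolerance) {
  tol <- tolerance / 255
  col <- color / 255
  abs(img[, , 1] - col[1]) <= tol &
    abs(img[, , 2] - col[2]) <= tol &
    abs(img[, , 3] - col[3]) <= tol
}

# normalized cross-correlation of the binary patch around `ctr` against
# cross and x templates; returns the better glyph or NULL below threshold
glyph_match <- function(hit, ctr, threshold, m = 4L) {
  nr <- nrow(hit); nc <- ncol(hit)
  r <- round(ctr[1]); c <- round(ctr[2])
  rows <- (r - m):(r + m); cols <- (c - m):(c + m)
  patch <- matrix(0, 2 * m + 1, 2 * m + 1)
  ok_r <- rows >= 1 & rows <= nr; ok_c <- cols >= 1 & cols <= nc
  patch[ok_r, ok_c] <- hit[rows[ok_r], cols[ok_c]] * 1
  if (stats::sd(patch) == 0) return(NULL)
  d <- -m:m
  cross <- outer(d, d, function(i, j) as.numeric(i == 0 | j == 0))
  xgl <- outer(d, d, function(i, j) as.numeric(abs(i) == abs(j)))
  ncc_cross <- stats::cor(as.vector(patch), as.vector(cross))
  ncc_x <- stats::cor(as.vector(patch), as.vector(xgl))
  best <- max(ncc_cross, ncc_x)
  if (!is.finite(best) || best < threshold) return(NULL)
  if (ncc_cross >= ncc_x) "cross" else "x"
}

#' Detect a burned-in dotted measurement ellipse
#'
#' Centroids of palette-matched dot clusters are fed to
#' [fit_ellipse_direct()]; one reject-refit round discards clusters whose
#' radial distance from the first fit is an outlier (stray palette pixels,
#' overlapping glyphs), then refits on the inliers. The reconstructed mask
#' is the filled fitted ellipse.
#'
#' @param image RGB array.
#' @param palette palette to match (pass only the dot color when the image
#'   also carries calipers in another color).
#' @param label anatomical label for the reconstructed mask.
#' @return List with `ellipse` ([ellipse_params()]), `mask`
#'   ([label_mask()]), and `dots` (matrix of cluster centroids used).
#' @export
detect_dotted_ellipse <- function(image, palette = fb_palette(),
                                  label = "brain") {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    fb_stop("fb_format_error", "dotted-ellipse detection needs a color image")
  img <- normalize_rgb(image)
  hit <- matrix(FALSE, dim(img)[1], dim(img)[2])
  for (cname in names(palette$colors))
    hit <- hit | palette_match(img, palette$colors[[cname]], palette$tolerance)
  if (!any(hit))
    fb_stop("fb_degenerate_fit", "no palette-matched dots found")
  lab <- label_components8(hit)
  cents <- t(vapply(seq_len(max(lab)), function(k) {
    pix <- which(lab == k, arr.ind = TRUE)
    colMeans(pix)
  }, numeric(2)))
  if (nrow(cents) < 5)
    fb_stop("fb_degenerate_fit",
            "need at least 5 dot clusters, found %d", nrow(cents))
  fit1 <- fit_ellipse_direct(cents)
  resid <- radial_residual(cents, fit1)
  # outliers drag the initial fit and inflate every residual; the Tukey
  # upper fence adapts to that spread while a 2 px floor protects the
  # clean case from over-rejection
  q <- stats::quantile(resid, c(0.25, 0.75), names = FALSE)
  cutoff <- max(2, q[2] + 1.5 * (q[2] - q[1]))
  inliers <- resid <= cutoff
  fit <- if (sum(inliers) >= 5 && any(!inliers))
    fit_ellipse_direct(cents[inliers, , drop = FALSE]) else fit1
  grid <- fill_ellipse(dim(img)[1:2], fit)
  list(ellipse = fit, mask = label_mask(grid, label),
       dots = cents[if (any(!inliers)) inliers else TRUE, , drop = FALSE])
}

radial_residual <- function(pts, e) {
  th <- e$orientation_deg * pi / 180
  dx <- pts[, 2] - e$center_col; dy <- pts[, 1] - e$center_row
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  psi <- atan2(v, u)
  r_ell <- e$semi_major_a * e$semi_minor_b /
    sqrt((e$semi_minor_b * cos(psi))^2 + (e$semi_major_a * sin(psi))^2)
  abs(sqrt(u^2 + v^2) - r_ell)
}

fill_ellipse <- function(dims, e) {
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  th <- e$orientation_deg * pi / 180
  dx <- cc - e$center_col; dy <- rr - e$center_row
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / e$semi_major_a)^2 + (v / e$semi_minor_b)^2 <= 1
}

#' Parse OCR measurement text
#'
#' Regex-driven extraction of `ACRONYM value unit` lines as produced by an
#' OCR engine reading the measurement panel. Decimal comma and point are
#' both accepted; gestational age is recognized in the `"GA 31w4d"` form
#' (value returned in days, unit `weeks_days`). Unknown acronyms and
#' unit-inconsistent lines are skipped with a warning. The parser is pure:
#' idempotent and order-preserving.
#'
#' @param lines character vector of text lines.
#' @return data.frame with columns `acronym`, `value`, `unit`.
#' @export
parse_measurement_text <- function(lines) {
  out <- list()
  len_units <- c("cm", "mm")
  for (line in lines) {
    m <- regmatches(line, regexec(
      "\\b(GA)\\s*:?\\s*([0-9]+)\\s*[Ww]\\s*([0-9]+)\\s*[Dd]", line))[[1]]
    if (length(m) == 4) {
      out[[length(out) + 1L]] <- data.frame(
        acronym = "GA", value = 7 * as.numeric(m[3]) + as.numeric(m[4]),
        unit = "weeks_days", stringsAsFactors = FALSE)
      next
    }
    m <- regmatches(line, regexec(
      "^\\s*([A-Za-z]{2,4})\\s*:?\\s*([0-9]+(?:[.,][0-9]+)?)\\s*([A-Za-z]+)\\b",
      line))[[1]]
    if (length(m) != 4) next
    acro <- toupper(m[2])
    if (acro == "SDP") acro <- "AF"
    unit <- tolower(m[4])
    value <- as.numeric(sub(",", ".", m[3], fixed = TRUE))
    ok <- switch(acro,
      HC = , BPD = , AC = , FL = , AF = unit %in% len_units,
      EFW = unit == "g",
      FALSE)
    if (!isTRUE(ok) || !is.finite(value) || value <= 0) {
      fb_warn("fb_parse_warning", "skipping unparseable measurement '%s'",
              trimws(line))
      next
    }
    out[[length(out) + 1L]] <- data.frame(acronym = acro, value = value,
                                          unit = unit,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(acronym = character(), value = numeric(),
                      unit = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Length between a caliper pair
#'
#' Euclidean pixel distance between exactly two marks, converted with the
#' isotropic spacing (burned-in calipers can join any two pixels, so both
#' image directions are involved).
#'
#' @param marks list of exactly two [caliper_mark()]s.
#' @param row_spacing_cm,col_spacing_cm pixel spacing in cm/px.
#' @return Length in cm.
#' @export
caliper_pair_length <- function(marks, row_spacing_cm,
                                col_spacing_cm = row_spacing_cm) {
  if (!is.list(marks) || length(marks) != 2 ||
      !all(vapply(marks, inherits, logical(1), "caliper_mark")))
    fb_stop("fb_domain_error", "caliper_pair_length needs exactly two marks")
  d_px <- sqrt(sum((marks[[1]]$position - marks[[2]]$position)^2))
  px_to_cm(d_px, row_spacing_cm, col_spacing_cm, axis = "isotropic")
}
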