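# JSON report serialization. The schema is fixed; absent measurements are
# explicit nulls; NaN is forbidden (a measurement that could not be made is
# absent, never NaN). Number formatting is fixed (15 significant digits) so
# identical reports serialize byte-identically.

#' Write / read a biometry report
#'
#' `write_report()` serializes a [assemble_report()] result to a fixed JSON
#' schema; `read_report()` reconstructs an equal report object, so the pair
#' round-trips. Any NaN in the report is a serialization error.
#'
#' @param report a `biometry_report`.
#' @param path destination / source file.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns a `biometry_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "biometry_report"))
  doc <- serialize_report(report)
  assert_no_nan(doc, "report")
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", na = "null",
                         digits = I(15), pretty = TRUE)
  con <- tryCatch(file(path, "w"), error = function(e)
    fb_stop("fb_io_error", "cannot write report to %s: %s", path,
            conditionMessage(e)))
  on.exit(close(con))
  writeLines(as.character(js), con)
  invisible(path)
}

assert_no_nan <- function(x, where) {
  if (is.list(x)) {
    for (nm in names(x)) assert_no_nan(x[[nm]], paste(where, nm, sep = "."))
  } else if (is.numeric(x) && any(is.nan(x))) {
    fb_stop("fb_serialization_error", "NaN is forbidden in reports (at %s)",
            where)
  }
  invisible(TRUE)
}

serialize_report <- function(r) {
  ser_quality <- function(q) {
    if (is.null(q)) return(NULL)
    list(criterion_probs = if (is.null(q$criterion_probs)) NA else
           as.list(q$criterion_probs),
         zoom_ratio = q$zoom_ratio, zoom_conform = q$zoom_conform,
         angle_conform = if (is.null(q$angle_conform)) NA else q$angle_conform,
         confidence = q$confidence, composite = q$composite)
  }
  ser_ellipse <- function(e) {
    if (is.null(e)) return(NA)
    list(center_row = e$center_row, center_col = e$center_col,
         semi_major_a = e$semi_major_a, semi_minor_b = e$semi_minor_b,
         orientation_deg = e$orientation_deg)
  }
  ser_axis <- function(a) {
    if (is.null(a)) return(NA)
    list(length_px = a$length_px, angle_deg = a$angle_deg,
         endpoints = unname(a$endpoints))
  }
  ser_plane <- function(p) {
    if (is.null(p)) return(NA)
    list(plane = p$plane, frame_index = p$frame_index,
         HC_cm = p$HC_cm %||% NA, BPD_cm = p$BPD_cm %||% NA,
         AC_cm = p$AC_cm %||% NA, FL_cm = p$FL_cm %||% NA,
         quality = ser_quality(p$quality),
         ellipse = ser_ellipse(p$ellipse), axis = ser_axis(p$axis),
         calipers = if (is.null(p$calipers)) NA else unname(p$calipers))
  }
  list(
    planes = list(cephalic = ser_plane(r$planes$cephalic),
                  abdominal = ser_plane(r$planes$abdominal),
                  femoral = ser_plane(r$planes$femoral)),
    sdp = if (is.null(r$sdp)) NA else
      list(depth_cm = r$sdp$depth_cm, afv_category = r$sdp$afv_category,
           frame_index = r$sdp$frame_index,
           pocket = list(depth_px = r$sdp$pocket$depth_px,
                         top_row = r$sdp$pocket$top_row,
                         bottom_row = r$sdp$pocket$bottom_row,
                         column_ref = r$sdp$pocket$column_ref)),
    efw_g = r$efw_g %||% NA,
    ga_days = r$ga_days %||% NA,
    ga_weeks_days = r$ga_weeks_days %||% NA,
    provenance = r$provenance)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) fb_stop("fb_io_error", "no such file: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  de_na <- function(x) if (length(x) == 1 && all(is.na(x))) NULL else x
  de_quality <- function(q) {
    if (is.null(q)) return(NULL)
    probs <- de_na(q$criterion_probs)
    quality_assessment(if (is.null(probs)) NULL else unlist(probs),
                       q$zoom_ratio, q$zoom_conform,
                       de_na(q$angle_conform), q$confidence, q$composite)
  }
  de_plane <- function(p) {
    if (is.null(de_na(p))) return(NULL)
    ell <- de_na(p$ellipse)
    if (!is.null(ell))
      ell <- ellipse_params(ell$center_row, ell$center_col, ell$semi_major_a,
                            ell$semi_minor_b, ell$orientation_deg)
    ax <- de_na(p$axis)
    if (!is.null(ax))
      ax <- axis_measurement(ax$length_px, ax$angle_deg,
                             matrix(ax$endpoints, ncol = 2,
                                    dimnames = list(NULL, c("row", "col"))))
    structure(list(plane = p$plane, frame_index = p$frame_index,
                   quality = de_quality(p$quality),
                   ellipse = ell, axis = ax,
                   HC_cm = de_na(p$HC_cm), BPD_cm = de_na(p$BPD_cm),
                   AC_cm = de_na(p$AC_cm), FL_cm = de_na(p$FL_cm),
                   calipers = if (is.null(de_na(p$calipers))) NULL else
                     matrix(p$calipers, ncol = 2,
                            dimnames = list(NULL, c("row", "col")))),
              class = "plane_measurement")
  }
  sdp <- de_na(doc$sdp)
  if (!is.null(sdp)) {
    sdp <- structure(list(
      depth_cm = sdp$depth_cm, frame_index = sdp$frame_index,
      pocket = structure(sdp$pocket, class = "depth_measurement"),
      afv_category = sdp$afv_category), class = "sdp_measurement")
  }
  structure(list(
    planes = list(cephalic = de_plane(doc$planes$cephalic),
                  abdominal = de_plane(doc$planes$abdominal),
                  femoral = de_plane(doc$planes$femoral)),
    sdp = sdp,
    efw_g = de_na(doc$efw_g), ga_days = de_na(doc$ga_days),
    ga_weeks_days = de_na(doc$ga_weeks_days),
    provenance = doc$provenance), class = "biometry_report")
}
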