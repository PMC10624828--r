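# Loop -> measurement orchestration: every frame is segmented and scored,
# the best frame is selected, and only on that frame is the geometry
# extracted and converted to cm.

#' Measure a biometry loop
#'
#' For each frame of a cephalic, abdominal or femoral loop: segment, assess
#' the plane quality, compute the composite score; then select the best
#' frame and measure it. Head and abdomen go through contour -> direct
#' least-squares ellipse fit -> perimeter (HC or AC); the head additionally
#' yields BPD = 2 x semi-minor axis. The femur goes through the minimum-area
#' rotated rectangle (FL = long-side extent). Pixel lengths are converted to
#' cm with the loop's (isotropic) pixel spacing.
#'
#' @param loop a [cineloop()] of kind cephalic, abdominal or femoral.
#' @param backend an [fb_backend()].
#' @param config an [fb_config()].
#' @return A `plane_measurement` (list with `plane`, `frame_index`,
#'   `quality`, `ellipse`/`axis`, the plane's lengths in cm, and `calipers`),
#'   or [no_plane_found()] when no frame yields an instance.
#' @export
measure_biometry_loop <- function(loop, backend, config = fb_config()) {
  stopifnot(inherits(loop, "cineloop"), inherits(config, "fb_config"))
  if (!loop$kind %in% c("cephalic", "abdominal", "femoral"))
    fb_stop("fb_domain_error",
            "measure_biometry_loop expects a biometry loop, not '%s'",
            loop$kind)
  want_label <- label_for_kind(loop$kind)
  scored <- list()
  for (frame in loop$frames) {
    for (inst in segment_frame(frame, loop$kind, backend)) {
      if (inst$label != want_label) next
      cand <- assess_candidate(frame, inst, backend, config)
      cand$frame_index <- frame$index
      scored[[length(scored) + 1L]] <- cand
    }
  }
  best <- select_best_frame(scored)
  if (is_no_plane(best)) return(best)
  frame <- loop$frames[[match(best$frame_index,
                              vapply(loop$frames, `[[`, integer(1), "index"))]]
  measure_best_plane(loop$kind, frame, best, config)
}

assess_candidate <- function(frame, inst, backend, config) {
  zr <- zoom_ratio(inst$mask)
  zthr <- config$zoom_threshold[[inst$label]]
  zconf <- zr >= zthr
  axis <- NULL
  aconf <- NULL
  probs <- NULL
  if (inst$label == "femur") {
    axis <- principal_axis(inst$mask)
    aconf <- angle_conform(axis, config$femur_angle_threshold_deg)
  } else {
    probs <- classify_criteria(frame, inst, backend)
  }
  comp <- composite_score(
    criterion_probs = probs, zoom_conform = zconf, angle_conform = aconf,
    confidence = inst$confidence, weights = config$weights,
    zoom_raw = if (config$zoom_mode == "raw") zr else NULL)
  list(instance = inst, axis = axis,
       assessment = quality_assessment(probs, zr, zconf, aconf,
                                       inst$confidence, comp))
}

measure_best_plane <- function(kind, frame, best, config) {
  inst <- best$instance
  rs <- frame$row_spacing_cm; cs <- frame$col_spacing_cm
  out <- list(plane = kind, frame_index = best$frame_index,
              quality = best$assessment, ellipse = NULL, axis = NULL,
              HC_cm = NULL, BPD_cm = NULL, AC_cm = NULL, FL_cm = NULL,
              calipers = NULL)
  if (kind %in% c("cephalic", "abdominal")) {
    ell <- fit_ellipse_direct(outer_contour(inst$mask))
    circ_cm <- px_to_cm(ellipse_circumference(ell), rs, cs, "isotropic")
    out$ellipse <- ell
    if (kind == "cephalic") {
      out$HC_cm <- circ_cm
      out$BPD_cm <- px_to_cm(2 * ell$semi_minor_b, rs, cs, "isotropic")
      # minor axis is perpendicular to the major axis
      th <- (ell$orientation_deg + 90) * pi / 180
      out$calipers <- rbind(
        c(ell$center_row + ell$semi_minor_b * sin(th),
          ell$center_col + ell$semi_minor_b * cos(th)),
        c(ell$center_row - ell$semi_minor_b * sin(th),
          ell$center_col - ell$semi_minor_b * cos(th)))
    } else {
      out$AC_cm <- circ_cm
    }
  } else {
    ax <- best$axis %||% principal_axis(inst$mask)
    out$axis <- ax
    # caliper tips sit on the structure boundary (the iso-0.5 level), half a
    # pixel beyond the outermost pixel centers at each end -- the same
    # boundary convention the contour-based HC/AC measurements use
    out$FL_cm <- px_to_cm(ax$length_px + 1, rs, cs, "isotropic")
    out$calipers <- extend_endpoints(ax$endpoints, 0.5)
  }
  structure(out, class = "plane_measurement")
}

# push two endpoints apart by `by` px each along their joining direction
extend_endpoints <- function(ep, by) {
  v <- ep[2, ] - ep[1, ]
  n <- sqrt(sum(v^2))
  if (n < 1e-9) return(ep)
  u <- v / n
  rbind(ep[1, ] - by * u, ep[2, ] + by * u)
}

#' Measure the single deepest pocket across an amniotic sweep
#'
#' Every pocket instance in every frame is measured by [vertical_depth()]
#' and the maximum depth across all instances and frames is retained — the
#' automated analogue of sweeping through all pockets, picking the deepest,
#' and measuring it. Depths use the row spacing (vertical calipers), so
#' anisotropic spacing is fine here. Ties go to the earliest frame.
#'
#' @param loop amniotic [cineloop()].
#' @param backend an [fb_backend()].
#' @param config an [fb_config()].
#' @return An `sdp_measurement` (list with `depth_cm`, `frame_index`,
#'   `pocket`, `afv_category`) or [no_pocket_found()].
#' @export
measure_sdp_loop <- function(loop, backend, config = fb_config()) {
  stopifnot(inherits(loop, "cineloop"), inherits(config, "fb_config"))
  if (loop$kind != "amniotic")
    fb_stop("fb_domain_error", "measure_sdp_loop expects an amniotic loop")
  best <- NULL
  for (frame in loop$frames) {
    for (inst in segment_frame(frame, loop$kind, backend)) {
      if (inst$label != "af_pocket") next
      dm <- vertical_depth(inst$mask)
      d_cm <- px_to_cm(dm$depth_px, frame$row_spacing_cm,
                       frame$col_spacing_cm, axis = "row")
      if (is.null(best) || d_cm > best$depth_cm) {
        best <- list(depth_cm = d_cm, frame_index = frame$index, pocket = dm)
      }
    }
  }
  if (is.null(best)) return(no_pocket_found())
  best$afv_category <- classify_afv(best$depth_cm, config$formulas)
  structure(best, class = "sdp_measurement")
}

#' @rdname no_plane_found
#' @export
no_pocket_found <- function(reason = "no pocket instance in any frame") {
  structure(list(reason = reason), class = c("fb_no_pocket", "fb_no_plane"))
}

#' @rdname no_plane_found
#' @export
is_no_pocket <- function(x) inherits(x, "fb_no_pocket")

#' Hadlock estimated fetal weight
#'
#' The 3-parameter Hadlock log-polynomial:
#' \deqn{\log_{10} EFW = 1.335 - 0.0034\,AC\,FL + 0.0316\,BPD + 0.0457\,AC + 0.1623\,FL}
#' with AC, FL, BPD in cm and EFW in grams. Coefficients come from the
#' supplied [formula_config()]. Inputs must be nonnegative (zero is
#' admitted so the intercept identity `EFW = 10^c0` is exactly testable).
#'
#' @param ac_cm,fl_cm,bpd_cm abdominal circumference, femur length and
#'   biparietal diameter in cm.
#' @param config a [formula_config()].
#' @return Estimated fetal weight in grams.
#' @export
efw_hadlock <- function(ac_cm, fl_cm, bpd_cm, config = formula_config()) {
  stopifnot(inherits(config, "fb_formula_config"))
  check_number(ac_cm, "ac_cm", lower = 0)
  check_number(fl_cm, "fl_cm", lower = 0)
  check_number(bpd_cm, "bpd_cm", lower = 0)
  h <- config$hadlock
  log10_efw <- h[["c0"]] + h[["c_acfl"]] * ac_cm * fl_cm +
    h[["c_bpd"]] * bpd_cm + h[["c_ac"]] * ac_cm + h[["c_fl"]] * fl_cm
  10^log10_efw
}

#' Intergrowth gestational age (late pregnancy)
#'
#' \deqn{\ln GA = k_{hc2} (\ln HC)^2 + k_{flhc}\, FL \ln HC + k_0}
#' with GA in days. HC and FL must already be expressed in the unit the
#' configuration declares (`intergrowth_unit`, default mm); the pipeline
#' converts its cm-internal measurements before calling this. See
#' [formula_config()] for a caveat about the default intercept.
#'
#' @param hc,fl head circumference and femur length in the configured unit.
#' @param config a [formula_config()].
#' @return Gestational age in days.
#' @export
ga_intergrowth <- function(hc, fl, config = formula_config()) {
  stopifnot(inherits(config, "fb_formula_config"))
  check_number(hc, "hc", lower = 0, allow_equal_lower = FALSE)
  check_number(fl, "fl", lower = 0)
  k <- config$intergrowth
  exp(k[["k_hc2"]] * log(hc)^2 + k[["k_flhc"]] * fl * log(hc) + k[["k_0"]])
}

#' Render gestational age as weeks + days
#'
#' `floor(GA/7)` weeks plus the remainder rounded to whole days, with carry
#' when the remainder rounds to 7.
#'
#' @param ga_days gestational age in days.
#' @return String like `"31w4d"`.
#' @export
ga_weeks_days <- function(ga_days) {
  check_number(ga_days, "ga_days", lower = 0)
  w <- floor(ga_days / 7)
  d <- round(ga_days - 7 * w)
  if (d == 7) { w <- w + 1; d <- 0 }
  sprintf("%dw%dd", w, d)
}

#' Amniotic fluid volume category from SDP depth
#'
#' Strict inequalities, as the clinical rule is stated: depth < 2 cm is
#' oligohydramnios, depth > 8 cm polyhydramnios, anything in the closed
#' interval (boundaries included) is normal.
#'
#' @param depth_cm single-deepest-pocket depth in cm (nonnegative).
#' @param config a [formula_config()] carrying the two thresholds.
#' @return `"oligohydramnios"`, `"normal"` or `"polyhydramnios"`.
#' @export
classify_afv <- function(depth_cm, config = formula_config()) {
  stopifnot(inherits(config, "fb_formula_config"))
  check_number(depth_cm, "depth_cm", lower = 0)
  if (depth_cm < config$oligo_threshold_cm) "oligohydramnios"
  else if (depth_cm > config$poly_threshold_cm) "polyhydramnios"
  else "normal"
}

#' Assemble the clinical report
#'
#' Combines whatever plane and pocket measurements are available into one
#' report. EFW is computed only when AC, FL and BPD are all present; GA only
#' when HC and FL are present (converted to the configured Intergrowth input
#' unit first). Absent measurements stay absent — a partially complete
#' examination yields a partial, still-valid report.
#'
#' @param measurements named list with any subset of `cephalic`,
#'   `abdominal`, `femoral` (each a `plane_measurement` or a no-plane
#'   outcome) and `sdp` (an `sdp_measurement` or no-pocket outcome).
#' @param config an [fb_config()].
#' @param loops optional named character vector of loop source ids for
#'   provenance.
#' @return Object of class `"biometry_report"`.
#' @export
assemble_report <- function(measurements = list(), config = fb_config(),
                            loops = character()) {
  stopifnot(inherits(config, "fb_config"))
  get_plane <- function(nm) {
    m <- measurements[[nm]]
    if (is.null(m) || is_no_plane(m)) NULL else m
  }
  ceph <- get_plane("cephalic")
  abd <- get_plane("abdominal")
  fem <- get_plane("femoral")
  sdp <- measurements$sdp
  if (!is.null(sdp) && is_no_pocket(sdp)) sdp <- NULL

  efw <- NULL
  if (!is.null(abd$AC_cm) && !is.null(fem$FL_cm) && !is.null(ceph$BPD_cm))
    efw <- efw_hadlock(abd$AC_cm, fem$FL_cm, ceph$BPD_cm, config$formulas)
  ga <- NULL
  ga_wd <- NULL
  if (!is.null(ceph$HC_cm) && !is.null(fem$FL_cm)) {
    scale <- if (config$formulas$intergrowth_unit == "mm") 10 else 1
    ga <- ga_intergrowth(ceph$HC_cm * scale, fem$FL_cm * scale,
                         config$formulas)
    ga_wd <- ga_weeks_days(ga)
  }
  structure(list(
    planes = list(cephalic = ceph, abdominal = abd, femoral = fem),
    sdp = sdp, efw_g = efw, ga_days = ga, ga_weeks_days = ga_wd,
    provenance = list(
      config_hash = config_hash(config),
      version = as.character(utils::packageVersion("fetalbiom")),
      loops = as.list(loops))),
    class = "biometry_report")
}

#' @export
print.biometry_report <- function(x, ...) {
  cat("<biometry_report>\n")
  fmt <- function(v, unit) if (is.null(v)) "  -  " else sprintf("%.2f %s", v, unit)
  cat("  HC :", fmt(x$planes$cephalic$HC_cm, "cm"),
      " BPD:", fmt(x$planes$cephalic$BPD_cm, "cm"), "\n")
  cat("  AC :", fmt(x$planes$abdominal$AC_cm, "cm"),
      " FL :", fmt(x$planes$femoral$FL_cm, "cm"), "\n")
  cat("  SDP:", fmt(x$sdp$depth_cm, "cm"),
      if (!is.null(x$sdp)) sprintf(" (%s)", x$sdp$afv_category) else "", "\n")
  cat("  EFW:", fmt(x$efw_g, "g"),
      " GA :", if (is.null(x$ga_days)) "  -  " else
        sprintf("%.1f d (%s)", x$ga_days, x$ga_weeks_days), "\n")
  invisible(x)
}
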