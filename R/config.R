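#' Formula coefficients and clinical thresholds
#'
#' Bundles every coefficient used to turn raw biometry into clinical
#' quantities: the 3-parameter Hadlock log-polynomial for estimated fetal
#' weight (EFW, grams), the Intergrowth late-pregnancy formula for
#' gestational age (GA, days), and the single-deepest-pocket thresholds for
#' amniotic fluid categories. All coefficients are overridable so that users
#' can substitute alternative published fits without touching code.
#'
#' The Hadlock model is
#' \deqn{\log_{10} EFW = c_0 + c_{acfl} AC \cdot FL + c_{bpd} BPD + c_{ac} AC + c_{fl} FL}
#' with AC, FL, BPD in cm and EFW in grams. The Intergrowth model is
#' \deqn{\ln GA = k_{hc2} (\ln HC)^2 + k_{flhc} FL \ln HC + k_0}
#' with GA in days and HC, FL in the unit given by `intergrowth_unit`
#' (default mm, the convention of the formula's source).
#'
#' Note: with the default intercept `k_0 = 3.1813` the Intergrowth formula
#' returns implausibly low gestational ages for typical mm-scale inputs
#' (about 102 days for HC = 250 mm, FL = 50 mm). The default reproduces the
#' published coefficient set verbatim rather than silently correcting it;
#' override `k_0` if you require a recalibrated intercept.
#'
#' @param hadlock named numeric vector `c0`, `c_acfl`, `c_bpd`, `c_ac`, `c_fl`.
#' @param intergrowth named numeric vector `k_hc2`, `k_flhc`, `k_0`.
#' @param intergrowth_unit `"mm"` or `"cm"`: unit in which HC and FL are fed
#'   to the GA formula. Measured lengths (always cm internally) are converted
#'   on the way in.
#' @param oligo_threshold_cm,poly_threshold_cm SDP depth cutoffs in cm;
#'   depth strictly below the first is oligohydramnios, strictly above the
#'   second polyhydramnios.
#' @return A list of class `"fb_formula_config"`.
#' @export
#' @examples
#' cfg <- formula_config()
#' efw_hadlock(23.98, 5.28, 7.41, cfg)
formula_config <- function(hadlock = c(c0 = 1.335, c_acfl = -0.0034,
                                       c_bpd = 0.0316, c_ac = 0.0457,
                                       c_fl = 0.1623),
                           intergrowth = c(k_hc2 = 0.03243,
                                           k_flhc = 0.001644,
                                           k_0 = 3.1813),
                           intergrowth_unit = c("mm", "cm"),
                           oligo_threshold_cm = 2,
                           poly_threshold_cm = 8) {
  intergrowth_unit <- match.arg(intergrowth_unit)
  need <- function(x, keys, name) {
    if (!is.numeric(x) || !all(keys %in% names(x)))
      fb_stop("fb_config_error", "`%s` must be named numeric with %s",
              name, paste(keys, collapse = ", "))
    x[keys]
  }
  hadlock <- need(hadlock, c("c0", "c_acfl", "c_bpd", "c_ac", "c_fl"), "hadlock")
  intergrowth <- need(intergrowth, c("k_hc2", "k_flhc", "k_0"), "intergrowth")
  check_number(oligo_threshold_cm, "oligo_threshold_cm", lower = 0,
               allow_equal_lower = FALSE)
  check_number(poly_threshold_cm, "poly_threshold_cm", lower = oligo_threshold_cm,
               allow_equal_lower = FALSE)
  structure(list(hadlock = hadlock, intergrowth = intergrowth,
                 intergrowth_unit = intergrowth_unit,
                 oligo_threshold_cm = oligo_threshold_cm,
                 poly_threshold_cm = poly_threshold_cm),
            class = "fb_formula_config")
}

#' Pipeline configuration
#'
#' Central configuration object consumed by the measurement pipeline and the
#' annotation detectors. Defaults follow the standard-plane quality rules:
#' equal weights for the three composite-score components, a structure-area
#' zoom threshold of 0.5 of the image for head and abdomen ("occupying more
#' than half of total image"), and a 45 degree femur angle limit (strict
#' inequality). The femur zoom threshold defaults to 0.02: an elongated bone
#' can never cover half the image area, so its zoom rule is expressed on the
#' same area-fraction scale at a value matched to a well-zoomed femur.
#'
#' @param weights nonnegative weights `quality`, `zoom`, `confidence` for the
#'   composite score; normalized to sum 1 at use. All-zero is an error.
#' @param zoom_threshold per-structure minimum occupied-area fraction.
#' @param zoom_mode `"binary"` (Table-style conformity indicator enters the
#'   score) or `"raw"` (the area fraction itself enters).
#' @param femur_angle_threshold_deg femur-to-horizontal limit in degrees.
#' @param formulas a [formula_config()].
#' @param palette annotation overlay palette: a list with `colors` (named list
#'   of RGB triples, 0-255) and per-channel `tolerance`.
#' @param default_spacing_cm fallback pixel spacing (cm/px) applied when a
#'   loop source carries no spacing metadata; `NULL` means error instead.
#' @return A list of class `"fb_config"`.
#' @export
fb_config <- function(weights = c(quality = 1, zoom = 1, confidence = 1),
                      zoom_threshold = c(brain = 0.5, abdomen = 0.5,
                                         femur = 0.02),
                      zoom_mode = c("binary", "raw"),
                      femur_angle_threshold_deg = 45,
                      formulas = formula_config(),
                      palette = fb_palette(),
                      default_spacing_cm = NULL) {
  zoom_mode <- match.arg(zoom_mode)
  if (!is.numeric(weights) || length(weights) != 3L || any(weights < 0) ||
      !all(c("quality", "zoom", "confidence") %in% names(weights)))
    fb_stop("fb_config_error",
            "`weights` must be nonnegative, named quality/zoom/confidence")
  if (sum(weights) <= 0)
    fb_stop("fb_config_error", "composite-score weights must not all be zero")
  if (!all(c("brain", "abdomen", "femur") %in% names(zoom_threshold)))
    fb_stop("fb_config_error", "`zoom_threshold` needs brain, abdomen, femur")
  check_number(femur_angle_threshold_deg, "femur_angle_threshold_deg",
               lower = 0, upper = 90)
  if (!inherits(formulas, "fb_formula_config"))
    fb_stop("fb_config_error", "`formulas` must come from formula_config()")
  structure(list(weights = weights[c("quality", "zoom", "confidence")],
                 zoom_threshold = zoom_threshold,
                 zoom_mode = zoom_mode,
                 femur_angle_threshold_deg = femur_angle_threshold_deg,
                 formulas = formulas,
                 palette = palette,
                 default_spacing_cm = default_spacing_cm),
            class = "fb_config")
}

#' Default overlay palette for burned-in annotations
#'
#' Saturated vendor-style overlay colors with a generous per-channel
#' tolerance; ultrasound vendors vary, so treat these as configurable
#' defaults validated on synthetic renders, not as a standard.
#'
#' @param tolerance per-channel absolute tolerance on 0-255 scale.
#' @return list with `colors` (named RGB triples) and `tolerance`.
#' @export
fb_palette <- function(tolerance = 40) {
  list(colors = list(yellow  = c(255, 255, 0),
                     green   = c(0, 255, 0),
                     cyan    = c(0, 255, 255),
                     magenta = c(255, 0, 255)),
       tolerance = tolerance)
}

# Stable hash of a config for report provenance: canonical JSON -> md5.
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = 15)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# criterion vocabulary per plane ---------------------------------------------

criterion_set <- function(label) {
  switch(label,
    abdomen = c("A_KN", "A_PS", "A_SB", "A_SYM"),
    brain   = c("B_CB", "B_CS", "B_PVV", "B_SYM", "B_TH"),
    fb_stop("fb_unsupported_plane",
            "no quality-criterion classifier exists for label '%s'", label)
  )
}

LOOP_KINDS <- c("cephalic", "abdominal", "femoral", "amniotic")
MASK_LABELS <- c("brain", "abdomen", "femur", "af_pocket")

# which mask label belongs to which biometry loop kind
label_for_kind <- function(kind) {
  switch(kind, cephalic = "brain", abdominal = "abdomen", femoral = "femur",
         amniotic = "af_pocket",
         fb_stop("fb_domain_error", "unknown loop kind '%s'", kind))
}
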