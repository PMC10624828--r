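# Standard-plane quality scoring. Each candidate frame is scored by a
# composite of (i) the mean of its criterion probabilities, (ii) a zoom
# conformity term, and (iii) the backend's detection confidence; the
# highest-scoring frame in the loop becomes the measurement plane.

#' Zoom ratio of a structure
#'
#' Fraction of the image area occupied by the structure: the automatable
#' version of the "occupying more than half of total image" rule.
#'
#' @param mask a [label_mask()].
#' @return Area fraction in `[0, 1]`.
#' @export
zoom_ratio <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  mean(mask$grid)
}

#' Femur angle conformity
#'
#' Strict inequality, as the criterion is stated: a femur at exactly the
#' threshold angle does not conform.
#'
#' @param axis an `axis_measurement` from [principal_axis()].
#' @param threshold_deg limit in degrees (default 45).
#' @return `TRUE` when `|angle| < threshold`.
#' @export
angle_conform <- function(axis, threshold_deg = 45) {
  stopifnot(inherits(axis, "axis_measurement"))
  abs(axis$angle_deg) < threshold_deg
}

#' Composite plane-quality score
#'
#' Normalized weighted sum `w_q*Q + w_z*Z + w_c*C` where `Q` is the mean of
#' the criterion probabilities (for the femoral plane, which has no
#' criterion classifier, the angle-conformity indicator), `Z` the zoom term
#' (conformity indicator, or the raw area fraction when `zoom_raw` is
#' supplied), and `C` the backend confidence. Weights are normalized to sum
#' to one, so the score always lies in `[0, 1]` and is monotone
#' nondecreasing in each component.
#'
#' @param criterion_probs numeric vector of criterion probabilities, or
#'   `NULL` for the femoral plane.
#' @param zoom_conform logical zoom conformity.
#' @param angle_conform logical; used as `Q` when `criterion_probs` is NULL.
#' @param confidence backend confidence in `[0, 1]`.
#' @param weights nonnegative weights named quality/zoom/confidence.
#' @param zoom_raw optional raw area fraction replacing the binary zoom term.
#' @return Score in `[0, 1]`.
#' @export
composite_score <- function(criterion_probs = NULL, zoom_conform,
                            angle_conform = NULL, confidence,
                            weights = c(quality = 1, zoom = 1, confidence = 1),
                            zoom_raw = NULL) {
  if (!is.numeric(weights) || length(weights) != 3 || any(weights < 0))
    fb_stop("fb_config_error", "weights must be three nonnegative numbers")
  if (sum(weights) <= 0)
    fb_stop("fb_config_error", "composite-score weights must not all be zero")
  w <- weights / sum(weights)
  q <- if (!is.null(criterion_probs)) {
    if (any(criterion_probs < 0 | criterion_probs > 1))
      fb_stop("fb_domain_error", "criterion probabilities must lie in [0,1]")
    mean(criterion_probs)
  } else if (!is.null(angle_conform)) {
    as.numeric(isTRUE(angle_conform))
  } else {
    fb_stop("fb_domain_error",
            "need criterion_probs or angle_conform for the quality term")
  }
  z <- if (!is.null(zoom_raw)) {
    check_number(zoom_raw, "zoom_raw", lower = 0, upper = 1)
  } else {
    as.numeric(isTRUE(zoom_conform))
  }
  check_number(confidence, "confidence", lower = 0, upper = 1)
  unname(w[1] * q + w[2] * z + w[3] * confidence)
}

quality_assessment <- function(criterion_probs, zoom_ratio, zoom_conform,
                               angle_conform, confidence, composite) {
  structure(list(criterion_probs = criterion_probs, zoom_ratio = zoom_ratio,
                 zoom_conform = zoom_conform, angle_conform = angle_conform,
                 confidence = confidence, composite = composite),
            class = "fb_quality")
}

#' No-plane-found outcome
#'
#' A reportable outcome, not an error: a loop in which no frame produced a
#' usable instance yields this object, mirroring a protocol that tolerates
#' partially complete examinations.
#'
#' @param reason human-readable explanation.
#' @return Object of class `"fb_no_plane"`.
#' @export
no_plane_found <- function(reason = "no instance in any frame") {
  structure(list(reason = reason), class = "fb_no_plane")
}

#' @rdname no_plane_found
#' @param x object to test.
#' @export
is_no_plane <- function(x) inherits(x, "fb_no_plane")

#' Select the best-scoring frame
#'
#' Argmax of the composite score over scored candidates; ties are broken
#' toward the earliest frame index, which makes selection deterministic and
#' permutation-invariant.
#'
#' @param scored list of candidates, each a list with `frame_index`,
#'   `instance`, and `assessment` (an `fb_quality`).
#' @return The winning candidate, or [no_plane_found()] when `scored` is
#'   empty.
#' @export
select_best_frame <- function(scored) {
  if (length(scored) == 0) return(no_plane_found())
  comp <- vapply(scored, function(s) s$assessment$composite, numeric(1))
  idx <- vapply(scored, function(s) s$frame_index, numeric(1))
  best <- which(comp >= max(comp) - 0)            # exact ties only
  winner <- best[which.min(idx[best])]
  scored[[winner]]
}
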