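# Segmentation backend contract. The pipeline never segments anything
# itself: it consumes instances from a backend, which is either an external
# model adapter or the built-in phantom oracle. The backend is the only
# stochastic element the pipeline tolerates; given identical backend
# outputs, downstream measurements are identical.

#' Segmentation instance
#'
#' One labeled mask with a detection confidence: the contract between any
#' segmenter and the measurement pipeline. Confidences from different
#' backends are not comparable; the scalar is only required to lie in
#' `[0, 1]`.
#'
#' @param mask a [label_mask()].
#' @param label anatomical class; must equal the mask's label.
#' @param confidence detection score in `[0, 1]`.
#' @return Object of class `"seg_instance"`.
#' @export
seg_instance <- function(mask, label = mask$label, confidence = 1) {
  stopifnot(inherits(mask, "label_mask"))
  label <- match.arg(label, MASK_LABELS)
  if (!identical(label, mask$label))
    fb_stop("fb_domain_error", "instance label '%s' != mask label '%s'",
            label, mask$label)
  check_number(confidence, "confidence", lower = 0, upper = 1)
  structure(list(mask = mask, label = label, confidence = confidence),
            class = "seg_instance")
}

#' Define a segmentation/classification backend
#'
#' Adapter contract: `segment(frame, kind)` returns a list of
#' [seg_instance()] (possibly empty), `classify(frame, instance)` returns a
#' named probability vector over the criterion set of the instance's plane.
#' External deep-learning backends attach through this two-function
#' adapter; no model code ships with the package.
#'
#' @param segment,classify the two adapter functions.
#' @param name backend name used in provenance and error messages.
#' @return Object of class `"fb_backend"`.
#' @export
fb_backend <- function(segment, classify, name = "custom") {
  stopifnot(is.function(segment), is.function(classify))
  structure(list(segment = segment, classify = classify, name = name),
            class = "fb_backend")
}

.backend_registry <- new.env(parent = emptyenv())

#' Register / fetch a backend by name
#'
#' Simple process-level registry so configurations can refer to backends by
#' name (e.g. from the command line).
#'
#' @param name registry key.
#' @param backend an [fb_backend()].
#' @export
register_backend <- function(name, backend) {
  stopifnot(inherits(backend, "fb_backend"))
  assign(name, backend, envir = .backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
get_backend <- function(name) {
  if (!exists(name, envir = .backend_registry))
    fb_stop("fb_backend_unavailable", "no backend registered under '%s'", name)
  get(name, envir = .backend_registry)
}

#' Segment one frame through a backend
#'
#' Validates the adapter's output against the instance contract. Multiple
#' instances per frame are allowed (separate amniotic pockets, twins).
#'
#' @param frame a [us_frame()].
#' @param kind loop kind the frame belongs to.
#' @param backend an [fb_backend()].
#' @return List of [seg_instance()] (possibly empty).
#' @export
segment_frame <- function(frame, kind, backend) {
  stopifnot(inherits(frame, "us_frame"), inherits(backend, "fb_backend"))
  kind <- match.arg(kind, LOOP_KINDS)
  out <- backend$segment(frame, kind)
  if (!is.list(out) || !all(vapply(out, inherits, logical(1), "seg_instance")))
    fb_stop("fb_backend_error",
            "backend '%s' returned malformed instances", backend$name)
  out
}

#' Criterion probabilities for one instance
#'
#' Only head (brain) and abdomen planes have criterion classifiers; the
#' femoral plane's quality is derived entirely from the mask (zoom ratio and
#' angle), so a femur instance is an unsupported-plane error here.
#'
#' @inheritParams segment_frame
#' @param instance a [seg_instance()] with label `brain` or `abdomen`.
#' @return Named probability vector over the plane's criterion set
#'   (abdomen: A_KN, A_PS, A_SB, A_SYM; brain: B_CB, B_CS, B_PVV, B_SYM,
#'   B_TH).
#' @export
classify_criteria <- function(frame, instance, backend) {
  stopifnot(inherits(instance, "seg_instance"))
  want <- criterion_set(instance$label)  # errors for femur / af_pocket
  probs <- backend$classify(frame, instance)
  if (!is.numeric(probs) || !setequal(names(probs), want))
    fb_stop("fb_backend_error",
            "backend '%s' returned criteria %s, expected %s", backend$name,
            paste(names(probs), collapse = ","), paste(want, collapse = ","))
  probs <- probs[want]
  if (any(probs < 0 | probs > 1 | !is.finite(probs)))
    fb_stop("fb_backend_error", "criterion probabilities must lie in [0,1]")
  probs
}

#' Oracle backend for phantom loops
#'
#' Reads the phantom's planted label grids and flags directly, so the
#' pipeline runs end-to-end without any trained model. An optional
#' morphological degradation (erosion or dilation by a disc of radius
#' `degrade_px`) exercises robustness of the downstream geometry to
#' imperfect segmentation; the backend remains fully deterministic.
#'
#' @param truth the `truth` component returned by the phantom generators.
#' @param degrade_px integer radius (px) of the degradation, 0 = exact masks.
#' @param degrade_mode `"erode"` or `"dilate"`; ignored when `degrade_px = 0`.
#' @return An [fb_backend()].
#' @export
phantom_backend <- function(truth, degrade_px = 0,
                            degrade_mode = c("erode", "dilate")) {
  degrade_mode <- match.arg(degrade_mode)
  stopifnot(inherits(truth, "phantom_truth"))
  degrade <- function(grid) {
    if (degrade_px <= 0) return(grid)
    brush <- EBImage::makeBrush(2L * as.integer(degrade_px) + 1L, "disc")
    op <- if (degrade_mode == "erode") EBImage::erode else EBImage::dilate
    EBImage::imageData(op(grid * 1, brush)) > 0.5
  }
  segment <- function(frame, kind) {
    ft <- truth$frames[[frame$index + 1L]]
    if (is.null(ft)) return(list())
    out <- list()
    for (pl in ft$instances) {
      g <- degrade(pl$grid)
      if (!any(g)) next  # degradation erased the structure entirely
      out[[length(out) + 1L]] <-
        seg_instance(label_mask(g, pl$label), confidence = ft$confidence)
    }
    out
  }
  classify <- function(frame, instance) {
    ft <- truth$frames[[frame$index + 1L]]
    want <- criterion_set(instance$label)
    flags <- ft$flags[want]
    stats::setNames(as.numeric(flags), want)
  }
  fb_backend(segment, classify, name = "phantom-oracle")
}
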