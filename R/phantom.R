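# Synthetic cine-loop phantom with exact ground truth. The phantom is not a
# physically realistic ultrasound simulator: structures are ideal rasterized
# shapes, quality-criterion flags are planted metadata (the pipeline
# consumes classifier probabilities, so testing selection logic needs
# controllable flags, not realistic anatomy), and speckle is optional
# multiplicative gamma noise. What it does guarantee is an analytic truth
# value for every measurement the pipeline produces.

#' Phantom specification
#'
#' Describes one synthetic cine-loop: the structure geometry at full scale,
#' a per-frame scale trajectory peaking at a planted best frame, planted
#' quality-criterion flags (all true only at the best frame), a confidence
#' profile peaking at the best frame, and noise settings. Defaults emulate a
#' late-pregnancy acquisition at 0.05 cm/px on a 256x256 field: head ellipse
#' 120x90 px (BPD 9 cm), abdomen 115x100 px, femur 140 px (7 cm) at 20
#' degrees, and three amniotic pockets of 2.8/4.2/5.6 cm depth.
#'
#' @param kind loop kind.
#' @param n_frames number of frames.
#' @param dims image rows, cols.
#' @param spacing_cm isotropic pixel spacing.
#' @param best_frame 0-based index of the planted best frame.
#' @param ellipse list `a`, `b`, `theta_deg`, `center` (row, col) for
#'   cephalic/abdominal loops; semi-axes in px at full scale.
#' @param femur list `length_px` (cap-tip to cap-tip), `width_px`,
#'   `angle_deg`, `center` for femoral loops.
#' @param pockets for amniotic loops: list of pockets, each a list with
#'   `depth_cm`, `width_px`, `frame` (0-based), `top_row`, `left_col`.
#'   `NULL` lays out three default pockets automatically; `list()` plants
#'   none.
#' @param scale_profile numeric vector of per-frame scale factors
#'   (default `max(0.75, 1 - 0.04 |i - best|)`).
#' @param speckle logical; apply multiplicative speckle to the intensity
#'   frames (masks are unaffected).
#' @param speckle_shape gamma shape parameter of the unit-mean speckle.
#' @param seed integer seed; a fixed seed makes the phantom fully
#'   deterministic.
#' @return Object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(kind = c("cephalic", "abdominal", "femoral", "amniotic"),
                         n_frames = 20, dims = c(256, 256), spacing_cm = 0.05,
                         best_frame = n_frames %/% 2,
                         ellipse = NULL, femur = NULL, pockets = NULL,
                         scale_profile = NULL,
                         speckle = FALSE, speckle_shape = 4, seed = 1) {
  kind <- match.arg(kind)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(best_frame, "best_frame", lower = 0, upper = n_frames - 1)
  check_number(spacing_cm, "spacing_cm", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  ctr <- dims / 2
  if (is.null(ellipse) && kind == "cephalic")
    ellipse <- list(a = 120, b = 90, theta_deg = 15, center = ctr)
  if (is.null(ellipse) && kind == "abdominal")
    ellipse <- list(a = 115, b = 100, theta_deg = -10, center = ctr)
  if (is.null(femur) && kind == "femoral")
    femur <- list(length_px = 140, width_px = 14, angle_deg = 20, center = ctr)
  if (is.null(scale_profile)) {
    i <- seq_len(n_frames) - 1
    scale_profile <- pmax(0.75, 1 - 0.04 * abs(i - best_frame))
  }
  if (length(scale_profile) != n_frames)
    fb_stop("fb_spec_error", "scale_profile must have one entry per frame")
  if (kind %in% c("cephalic", "abdominal")) {
    th <- ellipse$theta_deg * pi / 180
    ext_r <- sqrt((ellipse$a * sin(th))^2 + (ellipse$b * cos(th))^2)
    ext_c <- sqrt((ellipse$a * cos(th))^2 + (ellipse$b * sin(th))^2)
    if (ellipse$center[1] - ext_r < 1 || ellipse$center[1] + ext_r > dims[1] ||
        ellipse$center[2] - ext_c < 1 || ellipse$center[2] + ext_c > dims[2])
      fb_stop("fb_spec_error", "ellipse exceeds image bounds")
  }
  if (kind == "femoral") {
    half <- femur$length_px / 2 + femur$width_px
    if (femur$center[1] - half < 1 || femur$center[1] + half > dims[1] ||
        femur$center[2] - half < 1 || femur$center[2] + half > dims[2])
      fb_stop("fb_spec_error", "femur exceeds image bounds")
  }
  if (kind == "amniotic" && is.null(pockets)) {
    pockets <- default_pockets(c(2.8, 4.2, 5.6), n_frames, dims, spacing_cm)
  }
  structure(list(kind = kind, n_frames = as.integer(n_frames),
                 dims = as.integer(dims), spacing_cm = spacing_cm,
                 best_frame = as.integer(best_frame), ellipse = ellipse,
                 femur = femur, pockets = pockets,
                 scale_profile = scale_profile, speckle = speckle,
                 speckle_shape = speckle_shape, seed = as.integer(seed)),
            class = "phantom_spec")
}

default_pockets <- function(depths_cm, n_frames, dims, spacing_cm) {
  lapply(seq_along(depths_cm), function(i) {
    d_px <- round(depths_cm[i] / spacing_cm)
    list(depth_cm = depths_cm[i], width_px = 40,
         frame = (i - 1L) %% n_frames,
         top_row = max(2L, (dims[1] - d_px) %/% 2L),
         left_col = 30L + (i - 1L) * 70L)
  })
}

# deterministic local RNG: evaluate expr under a seed, restore global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a biometry phantom loop
#'
#' Renders the structure across frames scaled by the trajectory. The planted
#' best frame carries all criterion flags true and the highest confidence;
#' every other frame has at least one criterion flag false (cycled
#' deterministically) and a lower confidence, so correct best-frame
#' selection is testable. Returned truth includes the analytic measurements
#' at the best frame, computed with the geometry module's own closed forms
#' (perimeter via the elliptic integral).
#'
#' @param spec a [phantom_spec()] of kind cephalic, abdominal or femoral.
#' @return List with `loop` (a [cineloop()]), `truth` (a `phantom_truth`
#'   carrying per-frame label grids, flags, confidences and the analytic
#'   measurements).
#' @export
generate_biometry_loop <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!spec$kind %in% c("cephalic", "abdominal", "femoral"))
    fb_stop("fb_spec_error", "use generate_af_loop() for amniotic phantoms")
  label <- label_for_kind(spec$kind)
  crits <- if (label == "femur") character() else criterion_set(label)
  frames <- vector("list", spec$n_frames)
  tframes <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    s <- spec$scale_profile[i]
    grid <- render_structure(spec, s)
    px <- matrix(30, spec$dims[1], spec$dims[2])
    px[grid] <- 180
    fr <- us_frame(i - 1L, px, spec$spacing_cm, spec$spacing_cm)
    if (spec$speckle)
      fr <- render_speckle(fr, seed = spec$seed * 1000L + i,
                           shape = spec$speckle_shape,
                           structure_grid = grid)
    frames[[i]] <- fr
    is_best <- (i - 1L) == spec$best_frame
    flags <- stats::setNames(rep(TRUE, length(crits)), crits)
    if (!is_best && length(crits) > 0)
      flags[((i - 1L) %% length(crits)) + 1L] <- FALSE
    conf <- if (is_best) 0.99 else
      max(0.5, 0.9 - 0.01 * abs((i - 1L) - spec$best_frame))
    tframes[[i]] <- list(instances = list(list(grid = grid, label = label)),
                         flags = flags, confidence = conf)
  }
  sb <- spec$scale_profile[spec$best_frame + 1L]
  analytic <- list()
  geometry <- list()
  if (spec$kind %in% c("cephalic", "abdominal")) {
    e <- ellipse_params(spec$ellipse$center[1], spec$ellipse$center[2],
                        spec$ellipse$a * sb, spec$ellipse$b * sb,
                        spec$ellipse$theta_deg)
    circ_cm <- ellipse_circumference(e) * spec$spacing_cm
    geometry$ellipse <- e
    if (spec$kind == "cephalic") {
      analytic$HC_cm <- circ_cm
      analytic$BPD_cm <- 2 * spec$ellipse$b * sb * spec$spacing_cm
    } else {
      analytic$AC_cm <- circ_cm
    }
  } else {
    analytic$FL_cm <- spec$femur$length_px * sb * spec$spacing_cm
    analytic$angle_deg <- spec$femur$angle_deg
    geometry$femur <- spec$femur
  }
  truth <- structure(list(kind = spec$kind, frames = tframes,
                          best_frame = spec$best_frame, analytic = analytic,
                          geometry = geometry, spacing_cm = spec$spacing_cm),
                     class = "phantom_truth")
  list(loop = cineloop(frames, spec$kind,
                       source_id = sprintf("phantom-%s-seed%d", spec$kind,
                                           spec$seed)),
       truth = truth)
}

render_structure <- function(spec, s) {
  nr <- spec$dims[1]; nc <- spec$dims[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (spec$kind %in% c("cephalic", "abdominal")) {
    e <- spec$ellipse
    th <- e$theta_deg * pi / 180
    dx <- cc - e$center[2]; dy <- rr - e$center[1]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / (e$a * s))^2 + (v / (e$b * s))^2 <= 1
  } else {
    f <- spec$femur
    th <- f$angle_deg * pi / 180
    hw <- f$width_px * s / 2
    hl <- f$length_px * s / 2 - hw  # segment half-length, caps add hw back
    dx <- cc - f$center[2]; dy <- rr - f$center[1]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    uc <- pmin(pmax(u, -hl), hl)    # distance to the capsule spine
    (u - uc)^2 + v^2 <= hw^2
  }
}

#' Generate an amniotic-sweep phantom loop
#'
#' Pockets are rendered as rectangular fluid blobs whose vertical pixel
#' extents equal the planted depths within one pixel (the planted depth is
#' quantized to whole pixels at rasterization). Pockets sharing a frame must
#' be disjoint. The truth SDP is the maximum planted depth.
#'
#' @param spec a [phantom_spec()] of kind amniotic.
#' @return Same shape as [generate_biometry_loop()].
#' @export
generate_af_loop <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind != "amniotic")
    fb_stop("fb_spec_error", "generate_af_loop needs an amniotic spec")
  nr <- spec$dims[1]; nc <- spec$dims[2]
  pockets <- spec$pockets %||% list()
  rects <- lapply(pockets, function(p) {
    d_px <- round(p$depth_cm / spec$spacing_cm)
    if (d_px < 1) fb_stop("fb_spec_error", "pocket shallower than one pixel")
    r0 <- p$top_row; r1 <- r0 + d_px
    c0 <- p$left_col; c1 <- c0 + p$width_px - 1L
    if (r0 < 1 || r1 > nr || c0 < 1 || c1 > nc)
      fb_stop("fb_spec_error", "pocket exceeds image bounds")
    list(frame = p$frame, r0 = r0, r1 = r1, c0 = c0, c1 = c1,
         depth_cm = p$depth_cm)
  })
  # disjointness within each frame
  by_frame <- split(rects, vapply(rects, `[[`, numeric(1), "frame"))
  for (grp in by_frame) {
    if (length(grp) < 2) next
    for (i in seq_len(length(grp) - 1)) for (j in (i + 1):length(grp)) {
      a <- grp[[i]]; b <- grp[[j]]
      if (a$r0 <= b$r1 && b$r0 <= a$r1 && a$c0 <= b$c1 && b$c0 <= a$c1)
        fb_stop("fb_spec_error",
                "pockets must be disjoint (overlap in frame %d)", a$frame)
    }
  }
  frames <- vector("list", spec$n_frames)
  tframes <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    px <- matrix(120, nr, nc)  # tissue background; fluid is anechoic (dark)
    insts <- list()
    for (rc in rects) {
      if (rc$frame != (i - 1L)) next
      grid <- matrix(FALSE, nr, nc)
      grid[rc$r0:rc$r1, rc$c0:rc$c1] <- TRUE
      px[grid] <- 10
      insts[[length(insts) + 1L]] <- list(grid = grid, label = "af_pocket")
    }
    fr <- us_frame(i - 1L, px, spec$spacing_cm, spec$spacing_cm)
    if (spec$speckle)
      fr <- render_speckle(fr, seed = spec$seed * 1000L + i,
                           shape = spec$speckle_shape)
    frames[[i]] <- fr
    tframes[[i]] <- list(instances = insts,
                         flags = stats::setNames(logical(0), character(0)),
                         confidence = 0.95)
  }
  depths <- vapply(rects, `[[`, numeric(1), "depth_cm")
  analytic <- if (length(depths)) list(SDP_cm = max(depths),
                                       depths_cm = depths) else list()
  truth <- structure(list(kind = "amniotic", frames = tframes,
                          best_frame = NA_integer_, analytic = analytic,
                          geometry = list(pockets = rects),
                          spacing_cm = spec$spacing_cm),
                     class = "phantom_truth")
  list(loop = cineloop(frames, "amniotic",
                       source_id = sprintf("phantom-amniotic-seed%d", spec$seed)),
       truth = truth)
}

#' Apply multiplicative speckle to a frame
#'
#' Unit-mean gamma noise (shape `shape`, scale `1/shape`) multiplies the
#' intensities; the planted structure boundaries are metadata and remain
#' untouched. Deterministic under a fixed seed.
#'
#' @param frame a [us_frame()].
#' @param seed integer seed.
#' @param shape gamma shape parameter (larger = smoother).
#' @param structure_grid unused hook for tissue-dependent noise maps;
#'   accepted for forward compatibility.
#' @return A new [us_frame()] with noisy intensities.
#' @export
render_speckle <- function(frame, seed, shape = 4, structure_grid = NULL) {
  stopifnot(inherits(frame, "us_frame"))
  if (shape <= 0) fb_stop("fb_spec_error", "speckle shape must be positive")
  noise <- with_seed(seed, matrix(
    stats::rgamma(length(frame$pixels), shape = shape, rate = shape),
    nrow(frame$pixels)))
  us_frame(frame$index, frame$pixels * noise,
           frame$row_spacing_cm, frame$col_spacing_cm)
}

#' Draw a randomized phantom case
#'
#' Samples one phantom specification from the study ranges used for
#' end-to-end recovery experiments: late-pregnancy structure sizes with
#' randomized orientation and position, and a random mask degradation
#' (erosion or dilation, radius 0-2 px) to emulate imperfect segmentation.
#' Fully deterministic for a given seed.
#'
#' @param kind loop kind.
#' @param seed integer seed.
#' @return List with `spec` (a [phantom_spec()]), `degrade_px` and
#'   `degrade_mode` (arguments for [phantom_backend()]).
#' @export
random_phantom_spec <- function(kind, seed) {
  kind <- match.arg(kind, LOOP_KINDS)
  with_seed(seed, {
    dims <- c(256, 256)
    ctr <- dims / 2 + stats::runif(2, -4, 4)
    spec <- switch(kind,
      cephalic = {
        a <- stats::runif(1, 105, 120)
        phantom_spec("cephalic", seed = seed,
                     ellipse = list(a = a, b = a * stats::runif(1, 0.72, 0.78),
                                    theta_deg = stats::runif(1, -45, 45),
                                    center = ctr))
      },
      abdominal = {
        a <- stats::runif(1, 105, 120)
        phantom_spec("abdominal", seed = seed,
                     ellipse = list(a = a, b = a * stats::runif(1, 0.85, 0.95),
                                    theta_deg = stats::runif(1, -30, 30),
                                    center = ctr))
      },
      femoral = phantom_spec("femoral", seed = seed,
                             femur = list(length_px = stats::runif(1, 120, 150),
                                          width_px = stats::runif(1, 12, 16),
                                          angle_deg = stats::runif(1, -40, 40),
                                          center = ctr)),
      amniotic = {
        n_pock <- sample(3:4, 1)
        dmax <- stats::runif(1, 4.8, 6.4)
        depths <- c(sort(stats::runif(n_pock - 1, 2.2, dmax - 0.3)), dmax)
        frames <- sample(0:19, n_pock)
        pockets <- lapply(seq_len(n_pock), function(i) {
          d_px <- round(depths[i] / 0.05)
          list(depth_cm = depths[i],
               width_px = round(stats::runif(1, 30, 55)),
               frame = frames[i],
               top_row = max(4L, (256L - d_px) %/% 2L),
               left_col = sample(20:180, 1))
        })
        phantom_spec("amniotic", seed = seed, pockets = pockets)
      })
    # balanced exposure to degradation radii: k cycles 0,1,2 with the case
    # seed (stratified design), the direction is drawn at random
    list(spec = spec,
         degrade_px = seed %% 3L,
         degrade_mode = sample(c("erode", "dilate"), 1))
  })
}
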