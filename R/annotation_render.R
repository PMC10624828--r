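# Fixture factory for the annotation-extraction module: draws vendor-style
# burned-in overlays (caliper crosses, a dotted measurement ellipse, text
# glyphs) onto a frame, at positions derived analytically from the phantom
# truth, so render -> detect round trips have an exact oracle.

# 3x5 bitmap font covering the characters used in measurement text
FONT3x5 <- list(
  "0" = "111101101101111", "1" = "010110010010111", "2" = "111001111100111",
  "3" = "111001111001111", "4" = "101101111001001", "5" = "111100111001111",
  "6" = "111100111101111", "7" = "111001001001001", "8" = "111101111101111",
  "9" = "111101111001111", "." = "000000000000010", " " = "000000000000000",
  "A" = "111101111101101", "B" = "110101110101110", "C" = "111100100100111",
  "D" = "110101101101110", "E" = "111100111100111", "F" = "111100111100100",
  "G" = "111100101101111", "H" = "101101111101101", "L" = "100100100100111",
  "M" = "101111111101101", "P" = "111101111100100", "S" = "111100111001111",
  "W" = "101101111111101"
)

#' Render burned-in annotations onto a frame
#'
#' Returns an RGB image (rows x cols x 3, values in `[0, 1]`) carrying the
#' grayscale frame plus: caliper crosses at the analytic caliper positions
#' (BPD minor-axis endpoints for a cephalic truth, femur endpoints for a
#' femoral truth, the vertical SDP pair for an amniotic truth), a dotted
#' ellipse along the planted ellipse for cephalic/abdominal truths, and the
#' measurement text rendered both as raster glyphs and as machine-readable
#' text lines. An empty truth yields the unmodified frame.
#'
#' @param frame a [us_frame()] (typically the truth's best frame).
#' @param truth a `phantom_truth` from the generators.
#' @param palette an [fb_palette()]; roles: yellow = calipers, cyan =
#'   ellipse dots, green = text.
#' @param n_dots number of dots on the dotted ellipse.
#' @return List with `image` (RGB array), `text_lines` (character),
#'   `calipers` (k x 2 matrix of true positions), `dots` (n x 2 matrix of
#'   true dot positions, or NULL).
#' @export
render_annotations <- function(frame, truth, palette = fb_palette(),
                               n_dots = 24) {
  stopifnot(inherits(frame, "us_frame"), inherits(truth, "phantom_truth"))
  g <- frame$pixels
  g <- g / max(g, 255)
  img <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  cols <- lapply(palette$colors, function(x) x / 255)
  calipers <- NULL
  dots <- NULL
  text_lines <- character()
  a <- truth$analytic
  sp <- truth$spacing_cm

  if (!is.null(truth$geometry$ellipse)) {
    e <- truth$geometry$ellipse
    phi <- seq(0, 2 * pi, length.out = n_dots + 1)[-(n_dots + 1)]
    th <- e$orientation_deg * pi / 180
    dr <- e$semi_major_a * cos(phi) * sin(th) +
      e$semi_minor_b * sin(phi) * cos(th)
    dc <- e$semi_major_a * cos(phi) * cos(th) -
      e$semi_minor_b * sin(phi) * sin(th)
    dots <- cbind(row = e$center_row + dr, col = e$center_col + dc)
    for (k in seq_len(nrow(dots)))
      img <- draw_dot(img, dots[k, 1], dots[k, 2], cols$cyan)
    if (!is.null(a$HC_cm)) {
      thm <- th + pi / 2
      calipers <- rbind(
        c(e$center_row + e$semi_minor_b * sin(thm),
          e$center_col + e$semi_minor_b * cos(thm)),
        c(e$center_row - e$semi_minor_b * sin(thm),
          e$center_col - e$semi_minor_b * cos(thm)))
      text_lines <- c(sprintf("HC %.2f CM", a$HC_cm),
                      sprintf("BPD %.2f CM", a$BPD_cm))
    } else {
      text_lines <- sprintf("AC %.2f CM", a$AC_cm)
    }
  } else if (!is.null(a$FL_cm)) {
    f <- truth$geometry$femur
    th <- f$angle_deg * pi / 180
    half <- a$FL_cm / sp / 2
    calipers <- rbind(
      c(f$center[1] - half * sin(th), f$center[2] - half * cos(th)),
      c(f$center[1] + half * sin(th), f$center[2] + half * cos(th)))
    text_lines <- sprintf("FL %.2f CM", a$FL_cm)
  } else if (!is.null(a$SDP_cm)) {
    rects <- truth$geometry$pockets
    deepest <- rects[[which.max(vapply(rects, `[[`, numeric(1), "depth_cm"))]]
    cmid <- (deepest$c0 + deepest$c1) / 2
    calipers <- rbind(c(deepest$r0, cmid), c(deepest$r1, cmid))
    text_lines <- sprintf("AF %.2f CM", a$SDP_cm)
  }
  if (!is.null(calipers)) {
    for (k in seq_len(nrow(calipers)))
      img <- draw_cross(img, calipers[k, 1], calipers[k, 2], cols$yellow)
    colnames(calipers) <- c("row", "col")
  }
  if (length(text_lines) > 0)
    img <- draw_text(img, text_lines, cols$green)
  list(image = img, text_lines = text_lines, calipers = calipers, dots = dots)
}

draw_cross <- function(img, r, c, color, arm = 4) {
  r <- round(r); c <- round(c)
  nr <- dim(img)[1]; nc <- dim(img)[2]
  for (d in -arm:arm) {
    if (r + d >= 1 && r + d <= nr && c >= 1 && c <= nc)
      img[r + d, c, ] <- color
    if (c + d >= 1 && c + d <= nc && r >= 1 && r <= nr)
      img[r, c + d, ] <- color
  }
  img
}

# 2x2 dot whose centroid lands within half a pixel of the true position
draw_dot <- function(img, r, c, color) {
  r0 <- round(r - 0.5); c0 <- round(c - 0.5)
  nr <- dim(img)[1]; nc <- dim(img)[2]
  for (dr in 0:1) for (dc in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) img[rr, cc, ] <- color
  }
  img
}

draw_text <- function(img, lines, color, origin = c(6, 6)) {
  r0 <- origin[1]
  for (line in lines) {
    c0 <- origin[2]
    for (ch in strsplit(toupper(line), "")[[1]]) {
      bits <- FONT3x5[[ch]]
      if (!is.null(bits)) {
        bm <- matrix(as.integer(strsplit(bits, "")[[1]]), nrow = 5,
                     byrow = TRUE)
        for (i in 1:5) for (j in 1:3) if (bm[i, j] == 1) {
          rr <- r0 + i - 1; cc <- c0 + j - 1
          if (rr <= dim(img)[1] && cc <= dim(img)[2]) img[rr, cc, ] <- color
        }
      }
      c0 <- c0 + 4
    }
    r0 <- r0 + 7
  }
  img
}
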