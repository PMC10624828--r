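# Geometry extraction from binary masks. Conventions used throughout:
#  * matrices are indexed [row, col] with row 1 at the top of the image;
#  * continuous point sets are two-column matrices (row, col);
#  * angles are measured from the image horizontal (the column axis), in
#    degrees, mapped into (-90, 90]; positive angles slope toward larger row
#    indices (downward on screen);
#  * lengths are pixel-center extents (max - min of pixel centers), matching
#    where a sonographer's caliper tips would sit.

#' Ellipse parameters
#'
#' Geometric parameters of a fitted ellipse: the carrier of head and
#' abdominal circumference (perimeter) and of the biparietal diameter
#' (2 x semi-minor axis).
#'
#' @param center_row,center_col ellipse center in pixel coordinates.
#' @param semi_major_a,semi_minor_b semi-axes in px, `a >= b > 0`.
#' @param orientation_deg major-axis angle to the image horizontal, in
#'   `(-90, 90]`.
#' @return An object of class `"ellipse_params"`.
#' @export
ellipse_params <- function(center_row, center_col, semi_major_a, semi_minor_b,
                           orientation_deg) {
  check_number(center_row, "center_row")
  check_number(center_col, "center_col")
  check_number(semi_major_a, "semi_major_a", lower = 0, allow_equal_lower = FALSE)
  check_number(semi_minor_b, "semi_minor_b", lower = 0)
  if (semi_minor_b > semi_major_a)
    fb_stop("fb_domain_error", "semi-axes must satisfy a >= b")
  orientation_deg <- wrap_angle(orientation_deg)
  structure(list(center_row = center_row, center_col = center_col,
                 semi_major_a = semi_major_a, semi_minor_b = semi_minor_b,
                 orientation_deg = orientation_deg),
            class = "ellipse_params")
}

# map an angle in degrees into (-90, 90] modulo 180
wrap_angle <- function(deg) {
  a <- deg %% 180
  if (a > 90) a <- a - 180
  if (a == -90) a <- 90
  a
}

#' Outer contour of a mask
#'
#' Closed sub-pixel boundary of the largest 8-connected component, traced at
#' iso-level 0.5 of the occupancy grid (marching-squares interpolation). The
#' boundary therefore runs half a pixel outside the outermost occupied pixel
#' centers, which is where the intensity edge of a filled structure lies.
#'
#' @param mask a [label_mask()]; must contain at least one occupied pixel
#'   and yield at least 8 boundary points.
#' @return Two-column matrix (`row`, `col`) of ordered boundary points.
#' @export
outer_contour <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  if (!any(mask$grid))
    fb_stop("fb_empty_structure", "cannot contour an empty mask")
  lab <- label_components8(mask$grid)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  g <- lab == keep
  nr <- nrow(g); nc <- ncol(g)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- as.numeric(g)
  cls <- grDevices::contourLines(x = 0:(nr + 1), y = 0:(nc + 1), z = z,
                                 levels = 0.5)
  if (length(cls) == 0)
    fb_stop("fb_empty_structure", "no iso-0.5 boundary found")
  span <- vapply(cls, function(cl) diff(range(cl$x)) * diff(range(cl$y)),
                 numeric(1))
  cl <- cls[[which.max(span)]]
  pts <- cbind(row = cl$x, col = cl$y)
  if (nrow(pts) < 8)
    fb_stop("fb_empty_structure",
            "structure too small to contour (%d boundary points)", nrow(pts))
  pts
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
label_components8 <- function(grid) {
  lab <- EBImage::imageData(EBImage::bwlabel(grid * 1))
  m <- max(lab)
  if (m <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # NW-SE diagonal contacts
  c_ <- lab[-1, -nc]; d <- lab[-nr, -1]   # SW-NE diagonal contacts
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c_[c_ > 0 & d > 0 & c_ != d], d[c_ > 0 & d > 0 & c_ != d]))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(m), find, integer(1))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0} to scattered
#' points by the algebraic direct least-squares method with the
#' ellipse-specificity constraint \eqn{4AC - B^2 = 1}, so the solution is
#' guaranteed to be an ellipse whenever one exists. The numerically stable
#' partitioned (block-eigenproblem) formulation is used, with the points
#' centered and isotropically scaled first; the classic single generalized
#' eigenproblem is badly conditioned for near-circular data.
#'
#' @param points two-column matrix (`row`, `col`) with at least 5
#'   non-collinear points, e.g. from [outer_contour()].
#' @return An [ellipse_params()].
#' @export
fit_ellipse_direct <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2 || nrow(points) < 5)
    fb_stop("fb_degenerate_fit",
            "ellipse fitting needs at least 5 points (got %d)", nrow(points))
  x <- points[, 2]; y <- points[, 1]
  mx <- mean(x); my <- mean(y)
  s <- sqrt(mean((x - mx)^2 + (y - my)^2))
  if (!is.finite(s) || s < 1e-12)
    fb_stop("fb_degenerate_fit", "points are coincident")
  xs <- (x - mx) / s; ys <- (y - my) / s

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    fb_stop("fb_degenerate_fit", "rank-deficient point scatter"))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M2)
  a1 <- NULL
  for (k in 1:3) {
    v <- eg$vectors[, k]
    if (is.complex(v)) {
      if (max(abs(Im(v))) > 1e-8) next
      v <- Re(v)
    }
    if (4 * v[1] * v[3] - v[2]^2 > 0) { a1 <- v; break }
  }
  if (is.null(a1))
    fb_stop("fb_degenerate_fit",
            "no ellipse satisfies the constraint for these points")
  coef <- c(a1, as.vector(Tm %*% a1))  # A B C D E F in scaled coordinates
  geo <- conic_to_geometric(coef)
  ellipse_params(center_row = geo$cy * s + my,
                 center_col = geo$cx * s + mx,
                 semi_major_a = geo$a * s,
                 semi_minor_b = geo$b * s,
                 orientation_deg = geo$theta_deg)
}

conic_to_geometric <- function(coef) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  Mm <- matrix(c(A, B / 2, B / 2, C), 2)
  if (det(Mm) <= 0)
    fb_stop("fb_degenerate_fit", "fitted conic is not an ellipse")
  ctr <- tryCatch(solve(2 * Mm, -c(D, E)), error = function(e)
    fb_stop("fb_degenerate_fit", "degenerate conic center"))
  k <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + F
  eg <- eigen(Mm, symmetric = TRUE)
  ax2 <- -k / eg$values
  if (any(ax2 <= 0))
    fb_stop("fb_degenerate_fit", "fitted conic has no real ellipse axes")
  ax <- sqrt(ax2)
  imax <- which.max(ax)
  v <- eg$vectors[, imax]
  theta <- atan2(v[2], v[1]) * 180 / pi
  list(cx = ctr[1], cy = ctr[2], a = max(ax), b = min(ax),
       theta_deg = wrap_angle(theta))
}

#' Ellipse circumference
#'
#' Perimeter of an ellipse via the complete elliptic integral of the second
#' kind, \eqn{C = 4 a E(e^2)} with \eqn{e^2 = 1 - b^2/a^2}, evaluated by the
#' arithmetic-geometric-mean method to near machine precision. No series
#' approximation is involved: the circle limit gives exactly `2*pi*r` and
#' the flat limit `b = 0` gives exactly `4a`.
#'
#' @param e an [ellipse_params()].
#' @return Perimeter in px.
#' @export
ellipse_circumference <- function(e) {
  stopifnot(inherits(e, "ellipse_params"))
  a <- e$semi_major_a; b <- e$semi_minor_b
  m <- 1 - (b / a)^2
  m <- min(max(m, 0), 1)
  4 * a * pracma::ellipke(m)$e
}

#' Principal axis of a mask
#'
#' Long axis of the minimum-area rotated rectangle enclosing the occupied
#' pixel centers: the femur-length primitive. Length is the pixel-center
#' extent along the rectangle's long side; the angle is that side's angle to
#' the horizontal in `(-90, 90]`; the reported endpoints are the midpoints
#' of the rectangle's short sides (the caliper positions). When the minimum
#' rectangle is square the axis closer to the horizontal is chosen, which
#' makes the result deterministic.
#'
#' @param mask nonempty [label_mask()].
#' @return Object of class `"axis_measurement"` with fields `length_px`,
#'   `angle_deg`, `endpoints` (2x2 matrix of (row, col)).
#' @export
principal_axis <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  occ <- which(mask$grid, arr.ind = TRUE)
  if (nrow(occ) == 0)
    fb_stop("fb_empty_structure", "cannot measure an empty mask")
  y <- occ[, 1]; x <- occ[, 2]
  if (nrow(occ) == 1) {
    return(axis_measurement(0, 0, rbind(c(y, x), c(y, x))))
  }
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  nh <- length(hull)
  best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    dx <- hx[j] - hx[i]; dy <- hy[j] - hy[i]
    if (dx == 0 && dy == 0) next
    phi <- atan2(dy, dx)
    cph <- cos(phi); sph <- sin(phi)
    u <- hx * cph + hy * sph
    v <- -hx * sph + hy * cph
    du <- diff(range(u)); dv <- diff(range(v))
    cand <- rect_candidate(du, dv, phi, u, v)
    if (is.null(best) ||
        cand$area < best$area - 1e-9 ||
        (abs(cand$area - best$area) <= 1e-9 && better_tie(cand, best))) {
      best <- cand
    }
  }
  if (is.null(best)) {  # all hull points coincident except rounding
    return(axis_measurement(0, 0, rbind(c(y[1], x[1]), c(y[1], x[1]))))
  }
  ep <- cbind(row = best$ep_y, col = best$ep_x)
  axis_measurement(best$len, best$angle, ep)
}

# build the candidate (length, angle, endpoints) for one rectangle
# orientation; the long side may be the u or the v direction, and when
# du == dv both are considered via the tie rule in the caller
rect_candidate <- function(du, dv, phi, u, v) {
  along_u <- if (abs(du - dv) <= 1e-9) {
    abs(wrap_angle(phi * 180 / pi)) <= abs(wrap_angle(phi * 180 / pi + 90))
  } else du > dv
  if (along_u) {
    len <- du
    ang <- wrap_angle(phi * 180 / pi)
    uc <- range(u); vc <- mean(range(v))
    ep_u <- uc; ep_v <- c(vc, vc)
  } else {
    len <- dv
    ang <- wrap_angle(phi * 180 / pi + 90)
    vc <- range(v); uc <- mean(range(u))
    ep_u <- c(uc, uc); ep_v <- vc
  }
  cph <- cos(phi); sph <- sin(phi)
  list(area = du * dv, len = len, angle = ang,
       ep_x = ep_u * cph - ep_v * sph,
       ep_y = ep_u * sph + ep_v * cph)
}

better_tie <- function(cand, best) {
  if (abs(cand$angle) < abs(best$angle) - 1e-9) return(TRUE)
  if (abs(abs(cand$angle) - abs(best$angle)) <= 1e-9 && cand$angle > best$angle)
    return(TRUE)
  FALSE
}

axis_measurement <- function(length_px, angle_deg, endpoints) {
  d <- sqrt(sum((endpoints[1, ] - endpoints[2, ])^2))
  if (abs(d - length_px) > 1e-6)
    fb_stop("fb_domain_error", "endpoint distance inconsistent with length")
  structure(list(length_px = length_px, angle_deg = angle_deg,
                 endpoints = endpoints),
            class = "axis_measurement")
}

#' Vertical pocket depth
#'
#' Depth of a fluid pocket as the vertical extent of its axis-aligned
#' bounding box: `max occupied row - min occupied row`, in px. The reported
#' reference column is the column holding the deepest single vertical chord
#' (ties broken toward the leftmost column); it is used for caliper display
#' only and does not influence the depth, which is deliberately the
#' bounding-box extent even for tilted pockets.
#'
#' @param mask nonempty [label_mask()].
#' @return Object of class `"depth_measurement"` with fields `depth_px`,
#'   `top_row`, `bottom_row`, `column_ref`.
#' @export
vertical_depth <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  occ <- which(mask$grid, arr.ind = TRUE)
  if (nrow(occ) == 0)
    fb_stop("fb_empty_structure", "cannot measure an empty mask")
  top <- min(occ[, 1]); bottom <- max(occ[, 1])
  chord <- tapply(occ[, 1], occ[, 2], function(r) max(r) - min(r))
  col_ref <- as.integer(names(chord)[which.max(chord)])
  structure(list(depth_px = as.numeric(bottom - top),
                 top_row = as.integer(top), bottom_row = as.integer(bottom),
                 column_ref = col_ref),
            class = "depth_measurement")
}

#' Convert a pixel length to centimeters
#'
#' Vertical depths use the row spacing; ellipse perimeters and rotated-axis
#' lengths mix both image directions and therefore require isotropic
#' spacing. Anisotropic spacing is an error for those, never silently
#' averaged.
#'
#' @param length_px length in px.
#' @param row_spacing_cm,col_spacing_cm pixel spacing in cm/px.
#' @param axis `"isotropic"` (requires the two spacings to agree within
#'   1e-6 cm), `"row"`, or `"col"`.
#' @return Length in cm.
#' @export
px_to_cm <- function(length_px, row_spacing_cm,
                     col_spacing_cm = row_spacing_cm,
                     axis = c("isotropic", "row", "col")) {
  axis <- match.arg(axis)
  check_number(length_px, "length_px", lower = 0)
  check_number(row_spacing_cm, "row_spacing_cm", lower = 0,
               allow_equal_lower = FALSE)
  check_number(col_spacing_cm, "col_spacing_cm", lower = 0,
               allow_equal_lower = FALSE)
  spacing <- switch(axis,
    row = row_spacing_cm,
    col = col_spacing_cm,
    isotropic = {
      if (abs(row_spacing_cm - col_spacing_cm) > 1e-6)
        fb_stop("fb_anisotropic_spacing",
                "isotropic conversion requires equal spacings (%g vs %g cm/px)",
                row_spacing_cm, col_spacing_cm)
      row_spacing_cm
    })
  length_px * spacing
}
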