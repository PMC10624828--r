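test_that("outer_contour traces the largest component at sub-pixel level", {
  g <- matrix(FALSE, 40, 40)
  g[10:30, 10:30] <- TRUE
  ct <- outer_contour(label_mask(g, "brain"))
  expect_gte(nrow(ct), 8)
  expect_equal(range(ct[, 1]), c(9.5, 30.5), tolerance = 1e-12)
  expect_equal(range(ct[, 2]), c(9.5, 30.5), tolerance = 1e-12)

  # a 5-px satellite must not influence the contour
  g2 <- g
  g2[2:3, 2:3] <- TRUE
  ct2 <- outer_contour(label_mask(g2, "brain"))
  expect_gte(min(ct2[, 1]), 9)

  g3 <- matrix(FALSE, 20, 20); g3[5, 5] <- TRUE
  expect_error(outer_contour(label_mask(g3, "brain")),
               class = "fb_empty_structure")
  expect_error(outer_contour(label_mask(matrix(FALSE, 20, 20), "brain")),
               class = "fb_empty_structure")
})

test_that("diagonally-touching pixels form one 8-connected component", {
  g <- matrix(FALSE, 30, 30)
  for (i in 5:20) g[i, i] <- TRUE            # pure diagonal line
  lab <- fetalbiom:::label_components8(g)
  expect_equal(max(lab), 1)
})

test_that("direct least-squares fit recovers noise-free conics exactly", {
  # circle: unique noise-free conic
  pts <- ellipse_points(50, 50, 10, 10, 0, n = 360)
  e <- fit_ellipse_direct(pts)
  expect_equal(e$center_row, 50, tolerance = 1e-6)
  expect_equal(e$center_col, 50, tolerance = 1e-6)
  expect_equal(e$semi_major_a, 10, tolerance = 1e-6)
  expect_equal(e$semi_minor_b, 10, tolerance = 1e-6)

  # general ellipses across orientations
  for (th in c(-60, -30, 0, 30, 60, 89)) {
    pts <- ellipse_points(100, 120, 80, 50, th, n = 100)
    e <- fit_ellipse_direct(pts)
    expect_equal(e$semi_major_a, 80, tolerance = 1e-6)
    expect_equal(e$semi_minor_b, 50, tolerance = 1e-6)
    expect_equal(e$orientation_deg, th, tolerance = 1e-4)
    expect_equal(e$center_row, 100, tolerance = 1e-6)
    expect_equal(e$center_col, 120, tolerance = 1e-6)
  }
})

test_that("fit is robust to isotropic noise: mean center error below 0.5 px", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    pts <- ellipse_points(120, 100, 80, 50, 30, n = 100, jitter_sd = 1)
    e <- fit_ellipse_direct(pts)
    sqrt((e$center_row - 120)^2 + (e$center_col - 100)^2)
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_ellipse_direct(cbind(1:4, 1:4)),
               class = "fb_degenerate_fit")
  # collinear
  expect_error(fit_ellipse_direct(cbind(1:20, 2 * (1:20) + 3)),
               class = "fb_degenerate_fit")
  # coincident
  expect_error(fit_ellipse_direct(matrix(5, 10, 2)),
               class = "fb_degenerate_fit")
})

test_that("fit is equivariant under translation and rotation", {
  set.seed(11)
  base <- ellipse_points(0, 0, 60, 35, 20, n = 80)
  e0 <- fit_ellipse_direct(base)
  # translation
  e1 <- fit_ellipse_direct(base + matrix(c(40, -25), nrow(base), 2,
                                         byrow = TRUE))
  expect_equal(e1$center_row, e0$center_row + 40, tolerance = 1e-9)
  expect_equal(e1$center_col, e0$center_col - 25, tolerance = 1e-9)
  expect_equal(e1$semi_major_a, e0$semi_major_a, tolerance = 1e-9)
  # rotation by alpha about the origin shifts the orientation by alpha
  alpha <- 25 * pi / 180
  rot <- cbind(row = base[, 1] * cos(alpha) + base[, 2] * sin(alpha),
               col = -base[, 1] * sin(alpha) + base[, 2] * cos(alpha))
  e2 <- fit_ellipse_direct(rot)
  expect_equal(e2$semi_major_a, e0$semi_major_a, tolerance = 1e-9)
  expect_equal(e2$semi_minor_b, e0$semi_minor_b, tolerance = 1e-9)
  expect_equal(e2$orientation_deg,
               fetalbiom:::wrap_angle(e0$orientation_deg + 25),
               tolerance = 1e-6)
})

test_that("circumference matches closed forms and quadrature", {
  r <- 7.3
  circ <- ellipse_circumference(ellipse_params(0, 0, r, r, 0))
  expect_equal(circ, 2 * pi * r, tolerance = 1e-12)
  flat <- ellipse_circumference(ellipse_params(0, 0, 5, 0, 0))
  expect_equal(flat, 20, tolerance = 1e-12)
  e21 <- ellipse_circumference(ellipse_params(0, 0, 2, 1, 0))
  expect_equal(e21, quad_circumference(2, 1), tolerance = 1e-10)
})

test_that("circumference is monotone in both axes and rotation-invariant", {
  a <- seq(10, 50, length.out = 9)
  c_a <- vapply(a, function(ai)
    ellipse_circumference(ellipse_params(0, 0, ai, 10, 0)), numeric(1))
  expect_true(all(diff(c_a) > 0))
  b <- seq(1, 30, length.out = 9)
  c_b <- vapply(b, function(bi)
    ellipse_circumference(ellipse_params(0, 0, 30, bi, 0)), numeric(1))
  expect_true(all(diff(c_b) > 0))
  for (th in c(-45, 10, 90)) {
    expect_identical(
      ellipse_circumference(ellipse_params(5, -3, 20, 8, th)),
      ellipse_circumference(ellipse_params(0, 0, 20, 8, 0)))
  }
})

test_that("principal axis measures rotated bars within raster tolerance", {
  g <- matrix(FALSE, 100, 100)
  g[20:80, 45:55] <- TRUE   # 61 x 11 vertical bar
  ax <- principal_axis(label_mask(g, "femur"))
  expect_equal(ax$length_px, 60)
  expect_equal(abs(ax$angle_deg), 90)
  expect_equal(sqrt(sum((ax$endpoints[1, ] - ax$endpoints[2, ])^2)),
               ax$length_px, tolerance = 1e-6)

  # rasterized rotations of the same bar
  for (ang in c(10, 30, -40)) {
    th <- ang * pi / 180
    rr <- matrix(1:151, 151, 151)
    cc <- matrix(1:151, 151, 151, byrow = TRUE)
    u <- (cc - 76) * cos(th) + (rr - 76) * sin(th)
    v <- -(cc - 76) * sin(th) + (rr - 76) * cos(th)
    gr <- abs(u) <= 30 & abs(v) <= 5
    ax <- principal_axis(label_mask(gr, "femur"))
    expect_equal(ax$length_px, 60, tolerance = 1.5)
    expect_equal(ax$angle_deg, ang, tolerance = 2)
  }
})

test_that("principal axis is translation-invariant", {
  g <- matrix(FALSE, 120, 120)
  g[10:40, 20:26] <- TRUE
  ax1 <- principal_axis(label_mask(g, "femur"))
  g2 <- matrix(FALSE, 120, 120)
  g2[60:90, 80:86] <- TRUE
  ax2 <- principal_axis(label_mask(g2, "femur"))
  expect_equal(ax1$length_px, ax2$length_px)
  expect_equal(ax1$angle_deg, ax2$angle_deg)
})

test_that("square min-area rectangle resolves deterministically", {
  # symmetric plus sign: every candidate box is square; the tie rule picks
  # the axis closest to horizontal, deterministically
  g <- matrix(FALSE, 101, 101)
  g[46:56, 21:81] <- TRUE
  g[21:81, 46:56] <- TRUE
  ax1 <- principal_axis(label_mask(g, "femur"))
  ax2 <- principal_axis(label_mask(g, "femur"))
  expect_identical(ax1, ax2)
  # brute-force the minimum rectangle area over a fine angle grid and check
  # the returned rectangle attains it
  occ <- which(g, arr.ind = TRUE)
  areas <- vapply(seq(0, 89.9, by = 0.1), function(adeg) {
    th <- adeg * pi / 180
    u <- occ[, 2] * cos(th) + occ[, 1] * sin(th)
    v <- -occ[, 2] * sin(th) + occ[, 1] * cos(th)
    diff(range(u)) * diff(range(v))
  }, numeric(1))
  # the plus sign's minimal box is the diagonal one; its long side length
  best_th <- seq(0, 89.9, by = 0.1)[which.min(areas)]
  th <- best_th * pi / 180
  u <- occ[, 2] * cos(th) + occ[, 1] * sin(th)
  expect_equal(ax1$length_px, diff(range(u)), tolerance = 1)
})

test_that("empty masks raise empty-structure errors", {
  m <- label_mask(matrix(FALSE, 20, 20), "femur")
  expect_error(principal_axis(m), class = "fb_empty_structure")
  expect_error(vertical_depth(m), class = "fb_empty_structure")
})

test_that("vertical depth is the bounding-box row extent", {
  g <- matrix(FALSE, 100, 100)
  g[10:60, 30:40] <- TRUE
  d <- vertical_depth(label_mask(g, "af_pocket"))
  expect_equal(d$depth_px, 50)
  expect_equal(d$top_row, 10)
  expect_equal(d$bottom_row, 60)

  g1 <- matrix(FALSE, 50, 50); g1[25, 10:30] <- TRUE
  expect_equal(vertical_depth(label_mask(g1, "af_pocket"))$depth_px, 0)

  # staggered pocket: bounding-box extent, not the longest single chord
  gl <- matrix(FALSE, 100, 100)
  gl[10:15, 40:60] <- TRUE
  gl[50:55, 10:30] <- TRUE
  dl <- vertical_depth(label_mask(gl, "af_pocket"))
  expect_equal(dl$depth_px, 45)
  chords <- apply(gl, 2, function(col) {
    w <- which(col); if (length(w)) max(w) - min(w) else -Inf
  })
  expect_equal(max(chords), 5)   # every single chord is much shorter
  expect_equal(dl$column_ref, which.max(chords))
})

test_that("vertical depth equals the brute-force oracle on random blobs", {
  for (s in 1:25) {
    g <- random_blob(s)
    d <- vertical_depth(label_mask(g, "af_pocket"))
    expect_equal(d$depth_px, brute_depth(g))
  }
})

test_that("pixel-to-cm conversion enforces isotropy where required", {
  expect_equal(px_to_cm(50, 0.05), 2.5)
  expect_equal(px_to_cm(0, 0.05), 0)
  expect_equal(px_to_cm(10, 0.05, 0.06, axis = "row"), 0.5)
  expect_equal(px_to_cm(10, 0.05, 0.06, axis = "col"), 0.6)
  expect_error(px_to_cm(10, 0.05, 0.06, axis = "isotropic"),
               class = "fb_anisotropic_spacing")
})
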