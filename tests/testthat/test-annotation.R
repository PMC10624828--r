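gray_rgb <- function(dims = c(200, 200), level = 0.3) {
  array(level, c(dims, 3))
}

test_that("rendered caliper crosses are detected within one pixel", {
  img <- gray_rgb()
  yellow <- c(1, 1, 0)
  img <- fetalbiom:::draw_cross(img, 100, 50, yellow)
  img <- fetalbiom:::draw_cross(img, 100, 150, yellow)
  pal <- list(colors = list(yellow = c(255, 255, 0)), tolerance = 40)
  marks <- detect_calipers(img, pal)
  expect_length(marks, 2)
  pos <- do.call(rbind, lapply(marks, function(m) m$position))
  pos <- pos[order(pos[, 2]), ]
  expect_lt(max(abs(pos - rbind(c(100, 50), c(100, 150)))), 1)
  expect_true(all(vapply(marks, function(m) m$glyph, "") == "cross"))

  # grayscale input -> empty list
  expect_identical(detect_calipers(matrix(0.5, 50, 50), pal), list())
})

test_that("solid palette-colored shapes are rejected by the template gate", {
  img <- gray_rgb()
  img[80:95, 60:90, 1] <- 1; img[80:95, 60:90, 2] <- 1; img[80:95, 60:90, 3] <- 0
  pal <- list(colors = list(yellow = c(255, 255, 0)), tolerance = 40)
  expect_length(detect_calipers(img, pal), 0)
})

test_that("dotted ellipses are recovered, robust to stray palette pixels", {
  img <- gray_rgb(c(300, 300))
  cyan <- c(0, 1, 1)
  pts <- ellipse_points(150, 150, 80, 55, 15, n = 24)
  for (k in seq_len(nrow(pts)))
    img <- fetalbiom:::draw_dot(img, pts[k, 1], pts[k, 2], cyan)
  pal <- list(colors = list(cyan = c(0, 255, 255)), tolerance = 40)
  de <- detect_dotted_ellipse(img, pal)
  expect_equal(de$ellipse$semi_major_a, 80, tolerance = 0.01)
  expect_equal(de$ellipse$semi_minor_b, 55, tolerance = 0.01)
  expect_equal(de$ellipse$orientation_deg, 15, tolerance = 1)
  expect_s3_class(de$mask, "label_mask")
  expect_true(any(de$mask$grid))

  # two stray palette blobs far off the ellipse: reject-refit absorbs them
  img2 <- img
  img2 <- fetalbiom:::draw_dot(img2, 20, 20, cyan)
  img2 <- fetalbiom:::draw_dot(img2, 280, 30, cyan)
  de2 <- detect_dotted_ellipse(img2, pal)
  expect_equal(de2$ellipse$semi_major_a, 80, tolerance = 0.01)
  expect_equal(de2$ellipse$semi_minor_b, 55, tolerance = 0.01)

  # under-determined: 4 dots
  img3 <- gray_rgb()
  for (p in list(c(50, 50), c(50, 90), c(90, 50), c(90, 90)))
    img3 <- fetalbiom:::draw_dot(img3, p[1], p[2], cyan)
  expect_error(detect_dotted_ellipse(img3, pal), class = "fb_degenerate_fit")
})

test_that("measurement text parsing handles formats, locales, unknowns", {
  expect_warning(
    out <- parse_measurement_text(c("AC 23.98cm", "FL 5,28 cm", "EFP 123 cm",
                                    "EFW 1234 g", "GA 31w4d", "BPD 74 mm",
                                    "SDP 5.2 cm", "")),
    class = "fb_parse_warning")
  expect_equal(out$acronym, c("AC", "FL", "EFW", "GA", "BPD", "AF"))
  expect_equal(out$value, c(23.98, 5.28, 1234, 221, 74, 5.2))
  expect_equal(out$unit, c("cm", "cm", "g", "weeks_days", "mm", "cm"))
  # idempotent on its own textual rendering: parsing twice changes nothing
  again <- suppressWarnings(parse_measurement_text(
    c("AC 23.98cm", "FL 5,28 cm", "EFP 123 cm", "EFW 1234 g", "GA 31w4d",
      "BPD 74 mm", "SDP 5.2 cm", "")))
  expect_identical(out, again)
  # unit inconsistent with acronym is skipped
  expect_warning(bad <- parse_measurement_text("EFW 12 cm"),
                 class = "fb_parse_warning")
  expect_equal(nrow(bad), 0)
})

test_that("caliper pair length converts pixel distance with spacing", {
  m1 <- caliper_mark(c(100, 50)); m2 <- caliper_mark(c(100, 150))
  expect_equal(caliper_pair_length(list(m1, m2), 0.05), 5)
  expect_equal(caliper_pair_length(list(m1, m1), 0.05), 0)
  expect_error(caliper_pair_length(list(m1, m2, m1), 0.05),
               class = "fb_domain_error")
  expect_error(caliper_pair_length(list(m1, m2), 0.05, 0.06),
               class = "fb_anisotropic_spacing")
})

test_that("phantom annotations round-trip through the detectors", {
  sp <- phantom_spec("cephalic", seed = 21)
  ph <- generate_biometry_loop(sp)
  fr <- ph$loop$frames[[ph$truth$best_frame + 1]]
  ann <- render_annotations(fr, ph$truth)
  pal_y <- list(colors = list(yellow = c(255, 255, 0)), tolerance = 40)
  pal_c <- list(colors = list(cyan = c(0, 255, 255)), tolerance = 40)
  marks <- detect_calipers(ann$image, pal_y)
  expect_length(marks, 2)
  got <- do.call(rbind, lapply(marks, function(m) m$position))
  err <- vapply(seq_len(2), function(i)
    min(sqrt(rowSums((ann$calipers - matrix(got[i, ], 2, 2,
                                            byrow = TRUE))^2))),
    numeric(1))
  expect_lt(max(err), 1)
  de <- detect_dotted_ellipse(ann$image, pal_c)
  tru <- ph$truth$geometry$ellipse
  expect_equal(de$ellipse$semi_major_a, tru$semi_major_a, tolerance = 0.01)
  expect_equal(de$ellipse$semi_minor_b, tru$semi_minor_b, tolerance = 0.01)
  # the burned-in text parses back to the analytic measurements
  parsed <- parse_measurement_text(ann$text_lines)
  expect_equal(parsed$value[parsed$acronym == "HC"],
               ph$truth$analytic$HC_cm, tolerance = 0.005 / 33)
  # parsed BPD agrees with the distance between detected calipers
  bpd_from_marks <- caliper_pair_length(marks, 0.05)
  expect_equal(bpd_from_marks, ph$truth$analytic$BPD_cm, tolerance = 0.02)
})
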