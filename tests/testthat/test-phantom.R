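test_that("phantom generation is bit-identical under a fixed seed", {
  ph1 <- generate_biometry_loop(phantom_spec("cephalic", seed = 7,
                                             speckle = TRUE))
  ph2 <- generate_biometry_loop(phantom_spec("cephalic", seed = 7,
                                             speckle = TRUE))
  expect_identical(ph1$loop, ph2$loop)
  expect_identical(ph1$truth, ph2$truth)
  pha1 <- generate_af_loop(phantom_spec("amniotic", seed = 5))
  pha2 <- generate_af_loop(phantom_spec("amniotic", seed = 5))
  expect_identical(pha1$loop, pha2$loop)
})

test_that("analytic truth follows the planted geometry", {
  # larger canvas so a 160x120 px head fits
  sp <- phantom_spec("cephalic", dims = c(384, 384), seed = 1,
                     ellipse = list(a = 160, b = 120, theta_deg = 0,
                                    center = c(192, 192)))
  ph <- generate_biometry_loop(sp)
  expect_identical(ph$truth$analytic$BPD_cm, 2 * 120 * 0.05)
  e <- ph$truth$geometry$ellipse
  expect_equal(ph$truth$analytic$HC_cm,
               quad_circumference(e$semi_major_a, e$semi_minor_b) * 0.05,
               tolerance = 1e-10)
  # only the best frame carries all-true flags
  all_true <- vapply(ph$truth$frames, function(f) all(f$flags), logical(1))
  expect_identical(which(all_true) - 1L, ph$truth$best_frame)
  conf <- vapply(ph$truth$frames, function(f) f$confidence, numeric(1))
  expect_identical(which.max(conf) - 1L, ph$truth$best_frame)
})

test_that("amniotic truth is the maximum planted depth", {
  mkp <- function(d, fr, col) list(depth_cm = d, width_px = 40, frame = fr,
                                   top_row = 40L, left_col = col)
  sp <- phantom_spec("amniotic", n_frames = 4,
                     pockets = list(mkp(3.1, 0L, 20L), mkp(4.7, 1L, 20L),
                                    mkp(2.2, 2L, 20L)), seed = 1)
  ph <- generate_af_loop(sp)
  expect_equal(ph$truth$analytic$SDP_cm, 4.7)
  # rasterized pocket extent matches the planted depth within one pixel
  g <- ph$truth$frames[[2]]$instances[[1]]$grid
  expect_lt(abs(brute_depth(g) * 0.05 - 4.7), 0.05)

  empty <- generate_af_loop(phantom_spec("amniotic", pockets = list(),
                                         n_frames = 3, seed = 1))
  expect_length(empty$truth$analytic, 0)
  expect_s3_class(empty$loop, "cineloop")

  overlap <- list(mkp(3, 0L, 20L), mkp(3, 0L, 30L))  # columns overlap
  expect_error(generate_af_loop(phantom_spec("amniotic", n_frames = 2,
                                             pockets = overlap, seed = 1)),
               class = "fb_spec_error")

  # a planted 8.5 cm pocket classifies as polyhydramnios downstream
  deep <- phantom_spec("amniotic", n_frames = 2, dims = c(256, 256),
                       pockets = list(list(depth_cm = 8.5, width_px = 40,
                                           frame = 0L, top_row = 30L,
                                           left_col = 40L)), seed = 1)
  phd <- generate_af_loop(deep)
  smd <- measure_sdp_loop(phd$loop, phantom_backend(phd$truth))
  expect_equal(smd$afv_category, "polyhydramnios")
})

test_that("structures exceeding the image bounds are a spec error", {
  expect_error(phantom_spec("cephalic",
                            ellipse = list(a = 160, b = 120, theta_deg = 0,
                                           center = c(128, 128))),
               class = "fb_spec_error")
  expect_error(phantom_spec("femoral",
                            femur = list(length_px = 260, width_px = 14,
                                         angle_deg = 0, center = c(128, 128))),
               class = "fb_spec_error")
})

test_that("speckle is unit-mean, seeded, and optional", {
  fr <- us_frame(0, matrix(100, 128, 128), 0.05)
  s1 <- render_speckle(fr, seed = 3)
  s2 <- render_speckle(fr, seed = 3)
  expect_identical(s1$pixels, s2$pixels)
  expect_false(identical(s1$pixels, render_speckle(fr, seed = 4)$pixels))
  # law of large numbers: unit-mean noise leaves the mean within 2% at 16k px
  expect_equal(mean(s1$pixels) / 100, 1, tolerance = 0.02)
  # disabled speckle leaves the generator output untouched
  ph_clean <- generate_biometry_loop(phantom_spec("cephalic", seed = 2))
  expect_true(all(ph_clean$loop$frames[[1]]$pixels %in% c(30, 180)))
})

test_that("pipeline on an undegraded phantom reproduces the planted truth", {
  for (kind in c("cephalic", "abdominal", "femoral")) {
    sp <- phantom_spec(kind, seed = 13)
    ph <- generate_biometry_loop(sp)
    pm <- measure_biometry_loop(ph$loop, phantom_backend(ph$truth))
    expect_equal(pm$frame_index, ph$truth$best_frame)
    for (nm in intersect(names(ph$truth$analytic),
                         c("HC_cm", "BPD_cm", "AC_cm", "FL_cm"))) {
      key <- sub("_cm$", "", nm)
      expect_equal(pm[[paste0(key, "_cm")]], ph$truth$analytic[[nm]],
                   tolerance = 0.07 / ph$truth$analytic[[nm]])
    }
  }
})

test_that("empty truth renders no annotations", {
  sp <- phantom_spec("amniotic", pockets = list(), n_frames = 2, seed = 1)
  ph <- generate_af_loop(sp)
  fr <- ph$loop$frames[[1]]
  ann <- render_annotations(fr, ph$truth)
  expect_null(ann$calipers)
  expect_length(ann$text_lines, 0)
  base <- fr$pixels / max(fr$pixels, 255)
  expect_equal(ann$image[, , 1], base)
})
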