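test_that("difference sequence is the exact first difference", {
  expect_equal(difference_sequence(c(5, 5, 5, 5)), c(0, 0, 0))
  expect_equal(difference_sequence(c(1, 3, 6)), c(2, 3))
  expect_equal(difference_sequence(c(10, 10, 100, 100, 10)),
               c(0, 90, 0, -90))
  expect_error(difference_sequence(7), "at least 2")
})

test_that("sign runs segment into groups separated by zero points", {
  gr <- segment_groups(c(0, 90, 0, -90))
  expect_equal(gr$groups$sign, c(1, -1))
  expect_equal(gr$groups$start, c(2L, 4L))
  expect_equal(gr$groups$end, c(2L, 4L))
  expect_equal(gr$zero_points, c(1L, 3L))

  flat <- segment_groups(rep(0, 6))
  expect_equal(nrow(flat$groups), 0L)

  gr3 <- segment_groups(c(2, -3, 4))
  expect_equal(gr3$groups$sign, c(1, -1, 1))
  expect_length(gr3$zero_points, 0L)
})

test_that("noise floor merges speckle fragments but keeps true plateaus apart", {
  # a -1 blip inside a rising band is suppressed and the band re-fuses
  d <- c(5, 5, -1, 5, 0, -6)
  gr <- segment_groups(d, noise_floor = 2)
  expect_equal(gr$groups$sign, c(1, -1))
  expect_equal(gr$groups$start[1], 1L)
  expect_equal(gr$groups$end[1], 4L)
  # an exact-zero plateau between same-signed runs is a real boundary
  d2 <- c(5, 0, 5, -6)
  gr2 <- segment_groups(d2, noise_floor = 2)
  expect_equal(gr2$groups$sign, c(1, 1, -1))
})

test_that("leading/trailing gradient groups are discarded only when a wall pattern survives", {
  # profile that rises from its very first sample and falls at its last,
  # wrapped around a clean bright-wall pattern
  gray <- c(0, 50, 100, 100, 200, 200, 60, 60, 200, 200, 100, 100, 50, 0)
  gr <- discard_background_groups(segment_groups(difference_sequence(gray)))
  expect_equal(gr$groups$sign, c(1, -1, 1, -1))
  expect_gt(gr$groups$start[1], 1L)

  # nothing to discard: already exactly the wall pattern
  vp <- make_vessel_profile()
  gr2 <- segment_groups(difference_sequence(vp$gray))
  expect_identical(discard_background_groups(gr2)$groups, gr2$groups)

  # fewer than 2 groups: unchanged
  gr1 <- segment_groups(c(0, 3, 0))
  expect_identical(discard_background_groups(gr1)$groups, gr1$groups)

  # guard: dropping would destroy the only wall pattern -> keep
  ramp <- c(0, 100, 100, 30, 30, 120, 120, 10)
  gr3 <- segment_groups(difference_sequence(ramp))
  expect_identical(discard_background_groups(gr3)$groups, gr3$groups)
})

test_that("edges sit at the greatest-difference points of the paired groups", {
  vp <- make_vessel_profile(n = 220, wall_top = c(100, 110),
                            wall_bot = c(150, 160))
  es <- profile_edges(vp$gray)
  expect_equal(es$outer_top, 99.5)
  expect_equal(es$lumen_top, 110.5)
  expect_equal(es$lumen_bottom, 149.5)
  expect_equal(es$outer_bottom, 160.5)
  expect_equal(es$outer_bottom - es$outer_top, 61)
  expect_equal(es$lumen_bottom - es$lumen_top, 39)
  expect_equal(es$quality, 180 + 140 + 140 + 180)
  expect_equal(es$polarity, "bright")

  expect_error(profile_edges(rep(7, 50)), class = "octvessel_no_vessel")
})

test_that("dark-wall polarity is recognized via the inverted pattern", {
  vp <- make_vessel_profile(bg = 200, wall = 20, lumen = 160)
  es <- profile_edges(vp$gray)
  expect_equal(es$polarity, "dark")
  expect_equal(c(es$outer_top, es$lumen_top, es$lumen_bottom,
                 es$outer_bottom), vp$edges)
})

test_that("detected edges match the brute-force oracle on piecewise-constant profiles", {
  set.seed(42)
  for (i in 1:40) {
    vp <- random_vessel_profile(distractor = i %% 2 == 0)
    es <- profile_edges(vp$gray, noise_floor = 2)
    oracle <- brute_force_edges(vp$gray, noise_floor = 2)
    expect_equal(c(es$outer_top, es$lumen_top, es$lumen_bottom,
                   es$outer_bottom), oracle$edges)
    expect_equal(es$quality, oracle$score)
  }
})

test_that("vertical flip swaps top/bottom edges and preserves both extents", {
  set.seed(7)
  for (i in 1:15) {
    vp <- random_vessel_profile()
    n <- length(vp$gray)
    a <- profile_edges(vp$gray)
    b <- profile_edges(rev(vp$gray))
    expect_equal(b$outer_top, n + 1 - a$outer_bottom)
    expect_equal(b$outer_bottom, n + 1 - a$outer_top)
    expect_equal(b$lumen_top, n + 1 - a$lumen_bottom)
    expect_equal(b$outer_bottom - b$outer_top,
                 a$outer_bottom - a$outer_top)
    expect_equal(b$lumen_bottom - b$lumen_top,
                 a$lumen_bottom - a$lumen_top)
  }
})

test_that("speckled central-column edges land within 1 px of truth in >=95% of trials", {
  hits <- 0L
  for (s in 1:200) {
    ph <- generate_phantom(phantom_spec(120, 95, image_size = 256L,
                                        um_per_px = 1, speckle_sigma = 5,
                                        seed = s))
    gt <- ph$ground_truth
    es <- tryCatch(
      profile_edges(ph$cross$pixels[, gt$column_index]),
      error = function(e) NULL)
    ok <- !is.null(es) &&
      all(abs(c(es$outer_top, es$lumen_top, es$lumen_bottom,
                es$outer_bottom) -
              c(gt$outer_top, gt$lumen_top, gt$lumen_bottom,
                gt$outer_bottom)) <= 1)
    hits <- hits + ok
  }
  expect_gte(hits / 200, 0.95)
})

test_that("column scan recovers phantom diameters and respects the calibration", {
  ph <- generate_phantom(phantom_spec(160, 136, um_per_px = 0.5,
                                      center = c(256, 256)))
  # only the central chord equals the diameter; at this fine calibration
  # (radius 160 px) columns 30 px off-axis already lose ~3 px of chord, so
  # the scan window here is kept narrow around the vessel axis
  m <- scan_columns(phantom_roi(ph), ph$cross, center_fraction = 0.05)
  # noiseless: within one pixel-equivalent (rasterization bound)
  expect_lte(abs(m$outer_diameter - 160), 0.5 + 1e-9)
  expect_lte(abs(m$lumen_diameter - 136), 0.5 + 1e-9)
  expect_gt(m$n_columns_used, 1)

  # doubling the calibration exactly doubles reported micrometres
  cross2 <- vessel_cross_section(ph$cross$pixels, um_per_px = 1.0)
  m2 <- scan_columns(phantom_roi(ph), cross2, center_fraction = 0.05)
  expect_equal(m2$outer_diameter, 2 * m$outer_diameter)
  expect_equal(m2$lumen_diameter, 2 * m$lumen_diameter)
})

test_that("a single qualifying column is reported verbatim", {
  ph <- generate_phantom(phantom_spec(120, 95, um_per_px = 1))
  roi <- phantom_roi(ph, margin = 0L)
  w <- roi$roi_bounds[4] - roi$roi_bounds[2] + 1L
  m <- scan_columns(roi, ph$cross, center_fraction = 1 / w)
  expect_equal(m$n_columns_used, 1L)
  es <- profile_edges(
    ph$cross$pixels[roi$roi_bounds[1]:roi$roi_bounds[3],
                    m$columns$column[1]])
  expect_equal(m$outer_diameter, (es$outer_bottom - es$outer_top) * 1.0)
})

test_that("an off-centre scan window underestimates the diameter (chord effect)", {
  ph <- generate_phantom(phantom_spec(120, 95, um_per_px = 1,
                                      center = c(256, 286)))
  # window centred on the frame, 30 px off the vessel axis
  roi <- structure(list(enhanced = ph$cross$pixels, edge_map = NULL,
                        roi_bounds = c(186L, 196L, 326L, 316L)),
                   class = "roi_result")
  m <- scan_columns(roi, ph$cross, center_fraction = 0.5)
  expect_lt(m$outer_diameter, 120 - 2)
})

test_that("measurement failure carries per-column diagnostics", {
  flat <- vessel_cross_section(matrix(50, 64, 64), um_per_px = 1)
  roi <- structure(list(enhanced = flat$pixels, edge_map = NULL,
                        roi_bounds = c(1L, 1L, 64L, 64L)),
                   class = "roi_result")
  err <- tryCatch(scan_columns(roi, flat), error = identity)
  expect_s3_class(err, "octvessel_measurement_failed")
  expect_true(length(err$diagnostics) > 0)
})
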