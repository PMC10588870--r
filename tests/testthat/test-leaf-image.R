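test_that("segmentation recovers an exact synthetic rectangle", {
  img <- rect_scene(h = 200, w = 100)
  mask <- segment_leaf(img)
  expect_s3_class(mask, "leaf_mask")
  expect_identical(sum(mask$mask), 20000L)
})

test_that("segmentation fails cleanly on an empty scene", {
  blank <- leaf_image(matrix(1, 100, 100), 20)
  expect_error(segment_leaf(blank), "no leaf found")
})

test_that("segmentation is the identity on noise-free rendered leaves", {
  for (s in c(2, 9)) {
    img <- render_leaf(generate_leaf(random_leaf_spec(s)), ppcm = 20)
    mask <- segment_leaf(img)
    expect_identical(sum(mask$mask), as.integer(attr(img, "foreground_px")))
  }
})

test_that("border-touching clutter is excluded from the silhouette", {
  img <- rect_scene(h = 200, w = 100)
  img$pixels[1:40, ] <- 0            # ruler strip along the top border
  mask <- segment_leaf(img)
  expect_identical(sum(mask$mask), 20000L)
})

test_that("holes in the silhouette are filled by default", {
  img <- rect_scene(h = 200, w = 100)
  img$pixels[480:490, 430:440] <- 1  # specular hole
  expect_identical(sum(segment_leaf(img)$mask), 20000L)
  expect_lt(sum(segment_leaf(img, fill_holes = FALSE)$mask), 20000L)
})

test_that("area is pixel count over squared scale", {
  mask <- segment_leaf(rect_scene(h = 200, w = 100, ppcm = 20))
  expect_equal(measure_area(mask), 50)            # 20000 / 400
  mask$ppcm <- 10
  expect_equal(measure_area(mask), 200)
})

test_that("measured disc area matches the analytic circle", {
  mask <- segment_leaf(disc_scene(radius_px = 100, ppcm = 20))
  expect_equal(measure_area(mask), pi * 25, tolerance = 0.01)
})

test_that("axis-extent descriptors recover a rectangle and its rotation", {
  mask <- segment_leaf(rect_scene(h = 200, w = 80, ppcm = 20))
  d <- measure_descriptors(mask)                  # 10 cm x 4 cm
  expect_equal(d$L, 10, tolerance = 1 / 20 / 10)  # within one pixel
  expect_equal(d$W, 4, tolerance = 1 / 20 / 4)
  # rotated 37 degrees: extents invariant within 2%
  th <- 37 * pi / 180
  g <- expand.grid(r = 1:600, c = 1:600)
  u <- ((g$c - 300) * cos(th) - (300 - g$r) * sin(th)) / 20
  v <- ((g$c - 300) * sin(th) + (300 - g$r) * cos(th)) / 20
  m <- matrix(1, 600, 600)
  m[cbind(g$r, g$c)[abs(u) <= 5 & abs(v) <= 2, ]] <- 0
  d2 <- measure_descriptors(segment_leaf(leaf_image(m, 20)))
  expect_equal(d2$L, 10, tolerance = 0.02)
  expect_equal(d2$W, 4, tolerance = 0.02)
})

test_that("degenerate single-row masks are rejected", {
  m <- matrix(FALSE, 50, 50); m[25, 10:40] <- TRUE
  expect_error(measure_descriptors(leaf_mask(m, 20)), "degenerate")
})

test_that("tip-based descriptors track generator ground truth", {
  for (s in c(4, 9, 25)) {
    tru <- generate_leaf(random_leaf_spec(s))
    mask <- segment_leaf(render_leaf(tru, ppcm = 20))
    d <- measure_descriptors(mask, method = "tip-based")
    expect_equal(d$L, tru$L, tolerance = 0.05)
    expect_equal(d$W, tru$W, tolerance = 0.05)
    # occasional extra basal bump tolerated, never a missed lobe
    expect_gte(nrow(d$tips), tru$spec$n_lobes)
    expect_lte(nrow(d$tips), tru$spec$n_lobes + 1L)
  }
})

test_that("measured area is scale-consistent across ppcm", {
  tru <- generate_leaf(random_leaf_spec(13))
  a20 <- measure_area(segment_leaf(render_leaf(tru, ppcm = 20)))
  a40 <- measure_area(segment_leaf(render_leaf(tru, ppcm = 40)))
  expect_equal(a40 / a20, 1, tolerance = 0.01)
})

test_that("scale calibration reads a square fiducial", {
  m <- matrix(1, 600, 600); m[30 + 1:100, 30 + 1:100] <- 0
  expect_equal(calibrate_scale(leaf_image(m, 1), marker_cm = 2), 50)
  expect_equal(calibrate_scale(leaf_image(m, 1), marker_cm = 4), 25)
  expect_error(calibrate_scale(leaf_image(matrix(1, 200, 200), 1), 2),
               "marker not detected")
  # non-square clutter is not mistaken for the marker
  m2 <- matrix(1, 600, 600); m2[20 + 1:10, 20 + 1:120] <- 0
  expect_error(calibrate_scale(leaf_image(m2, 1), 2), "marker not detected")
})

test_that("a rendered fiducial calibrates the rendered scale", {
  tru <- generate_leaf(random_leaf_spec(6))
  img <- render_leaf(tru, ppcm = 20, fiducial_cm = 2)
  expect_equal(calibrate_scale(img, marker_cm = 2), 20, tolerance = 0.02)
  # and the leaf is still segmented, not the marker
  expect_equal(measure_area(segment_leaf(img)), tru$area, tolerance = 0.02)
})

test_that("leaf images round-trip through PNG", {
  tru <- generate_leaf(random_leaf_spec(2))
  img <- render_leaf(tru, ppcm = 20)
  tmp <- tempfile(fileext = ".png")
  write_image_png(img, tmp)
  back <- read_leaf_image(tmp, ppcm = 20)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_identical(sum(segment_leaf(back)$mask),
                   as.integer(attr(img, "foreground_px")))
})
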