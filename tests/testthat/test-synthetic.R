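test_that("rectangle-limit lobe reproduces known area and descriptors", {
  sp <- leaf_spec(n_lobes = 1, central_length = 10, lobe_width_ratio = 0.4,
                  shape_exponent = 0, base_radius_frac = 0)
  tr <- generate_leaf(sp)
  expect_equal(tr$area, 40, tolerance = 1e-3)
  expect_equal(tr$L, 10, tolerance = 1e-6)
  expect_equal(tr$W, 4, tolerance = 1e-3)
})

test_that("shoelace area agrees with an independent triangulation oracle", {
  skip_if_not_installed("pracma")
  for (s in c(3, 17, 42)) {
    tr <- generate_leaf(random_leaf_spec(s))
    expect_equal(tr$area, fan_triangulation_area(tr$polygon), tolerance = 1e-9)
    expect_equal(tr$area,
                 abs(pracma::polyarea(tr$polygon[, 1], tr$polygon[, 2])),
                 tolerance = 1e-9)
  }
})

test_that("shoelace area is invariant to vertex rotation and translation", {
  tr <- generate_leaf(random_leaf_spec(8))
  p <- tr$polygon
  rolled <- p[c(101:nrow(p), 1:100), ]
  expect_equal(shoelace_area(rolled), tr$area, tolerance = 1e-12)
  shifted <- sweep(p, 2, c(13.7, -2.9), `+`)
  expect_equal(shoelace_area(shifted), tr$area, tolerance = 1e-9)
  th <- 0.7; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(shoelace_area(p %*% rot), tr$area, tolerance = 1e-9)
})

test_that("a fixed spec generates a bit-identical polygon across runs", {
  sp1 <- leaf_spec(seed = 99, jitter = 0.05)
  sp2 <- leaf_spec(seed = 99, jitter = 0.05)
  expect_identical(generate_leaf(sp1)$polygon, generate_leaf(sp2)$polygon)
  expect_false(identical(generate_leaf(leaf_spec(seed = 100, jitter = 0.05))$polygon,
                         generate_leaf(sp1)$polygon))
})

test_that("degenerate specs are rejected", {
  expect_error(leaf_spec(n_lobes = 0), "n_lobes")
  expect_error(leaf_spec(central_length = -1))
  expect_error(leaf_spec(jitter = 0.1), "seed")
})

test_that("renderer foreground converges to ground-truth area with scale", {
  tr <- generate_leaf(leaf_spec(n_lobes = 1, central_length = 10,
                                lobe_width_ratio = 0.4, shape_exponent = 0,
                                base_radius_frac = 0))
  img20 <- render_leaf(tr, ppcm = 20)
  expect_equal(attr(img20, "foreground_px"), 40 * 400, tolerance = 0.02)
  err <- vapply(c(10, 40), function(pp) {
    im <- render_leaf(generate_leaf(random_leaf_spec(5)), ppcm = pp)
    tr5 <- generate_leaf(random_leaf_spec(5))
    abs(attr(im, "foreground_px") / pp^2 - tr5$area) / tr5$area
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_error(render_leaf(tr, ppcm = 20, canvas_cm = c(5, 5)), "canvas too small")
})

test_that("population sampler respects descriptor ranges and allometry", {
  pop <- generate_population(500, seed = 21, noise_sd = 0.05)
  expect_true(all(pop$L >= 6.28 & pop$L <= 29.26))
  expect_true(all(pop$W >= 5.00 & pop$W <= 40.58))
  expect_true(all(pop$LA > 0))
  # noiseless population recovers the generating slope exactly
  pop0 <- generate_population(40, seed = 22, noise_sd = 0)
  expect_equal(fit_through_origin(pop0$L * pop0$W, pop0$LA)$a, 0.42,
               tolerance = 1e-12)
  # seeded reproducibility
  expect_identical(generate_population(50, seed = 7),
                   generate_population(50, seed = 7))
})

test_that("leaf area disperses more than its linear descriptors", {
  pop <- generate_population(800, seed = 31, noise_sd = 0.1)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_gt(cv(pop$LA), cv(pop$L))
  expect_gt(cv(pop$LA), cv(pop$W))
})

test_that("a simulated plant shares one morphotype with varying leaf size", {
  sim <- simulate_plant(6, seed = 3)
  lob <- vapply(sim$truths, function(t) t$spec$n_lobes, integer(1))
  expect_length(unique(lob), 1L)
  expect_gt(diff(range(sim$records$L)), 0)
  expect_equal(sim$records$LA,
               vapply(sim$truths, `[[`, numeric(1), "area"))
})
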