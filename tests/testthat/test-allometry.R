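test_that("predictors are built per kind", {
  expect_equal(build_predictor(20, 30, "LxW"), 600)
  expect_equal(build_predictor(20, 30, "L*W"), 600)
  expect_equal(build_predictor(20, 30, "L+W"), 50)
  expect_equal(build_predictor(15, 30, "L/W"), 0.5)
  expect_equal(build_predictor(c(1, 2), c(3, 4), "W"), c(3, 4))
  expect_error(build_predictor(10, 20, "L^2"), "unknown predictor")
  expect_error(build_predictor(-1, 2, "L"), "positive")
})

test_that("correlation screen passes real predictors and drops noise", {
  la <- seq(10, 100, length.out = 10)
  sc <- screen_predictor(la, la)
  expect_true(sc$pass)
  expect_lt(sc$p_value, 1e-6)
  # scale invariance of correlation
  expect_true(screen_predictor(3.7 * la, la)$pass)
  # independent noise fails the screen in nearly all seeds
  fails <- vapply(1:40, function(s) withr::with_seed(s, {
    !screen_predictor(stats::runif(100), stats::runif(100))$pass
  }), logical(1))
  expect_gte(mean(fails), 0.95)
  expect_error(screen_predictor(rep(1, 5), 1:5), "zero-variance")
})

test_that("through-origin fit matches closed form and numeric oracle", {
  m <- fit_through_origin(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m$a, 2)
  expect_equal(m$RMSE, 0)
  expect_equal(m$R2, 1)
  # hand case: a = sum(x la) / sum(x^2) = 3/5
  m2 <- fit_through_origin(c(1, 2), c(1, 1))
  expect_equal(m2$a, 0.6)
  # numeric SSE minimization agrees
  opt <- stats::optimize(function(a) sum((c(1, 1) - a * c(1, 2))^2),
                         c(-10, 10), tol = 1e-12)$minimum
  expect_equal(m2$a, opt, tolerance = 1e-8)
  expect_error(fit_through_origin(c(0, 0), c(1, 2)), "identically zero")
})

test_that("slope is equivariant under rescaling of la and x", {
  withr::with_seed(5, {
    x <- stats::runif(30, 1, 10)
    la <- 0.4 * x * (1 + stats::rnorm(30, 0, 0.1))
  })
  a0 <- fit_through_origin(x, la)$a
  expect_equal(fit_through_origin(x, 3 * la)$a, 3 * a0)
  expect_equal(fit_through_origin(2 * x, la)$a, a0 / 2)
})

test_that("uncentered R2 variant is available", {
  withr::with_seed(6, {
    x <- stats::runif(20, 1, 10)
    la <- 2 * x + stats::rnorm(20, 0, 0.5)
  })
  m <- fit_through_origin(x, la, r2 = "uncentered")
  expect_equal(m$R2, 1 - sum((la - m$a * x)^2) / sum(la^2))
})

test_that("model selection ranks by R2, then RMSE, then simplicity", {
  mk <- function(kind, R2, RMSE) allometric_model(kind, a = 1, n = 10,
                                                  R2 = R2, RMSE = RMSE)
  models <- list(mk("L", 0.72, 44.3), mk("W", 0.69, 60.6),
                 mk("L+W", 0.71, 155.5), mk("LxW", 0.96, 17.5))
  expect_identical(select_best_model(models)$kind, "LxW")
  tie <- list(mk("L", 0.9, 10), mk("W", 0.9, 5))
  expect_identical(select_best_model(tie)$kind, "W")
  tie2 <- list(mk("W", 0.9, 5), mk("L", 0.9, 5))
  expect_identical(select_best_model(tie2)$kind, "L")
  expect_identical(select_best_model(models[2])$kind, "W")
  expect_error(select_best_model(list()), "no models")
})

test_that("prediction applies published coefficients through the origin", {
  m4 <- builtin_model("model4")
  expect_equal(m4$a, 0.42)
  expect_equal(predict_la(m4, L = 20, W = 30), 252)
  m1 <- builtin_model("model1")
  expect_equal(predict_la(m1, L = 10, W = 5), 115.8)
  # origin constraint: predictions vanish with either dimension
  expect_equal(predict_la(m4, L = 1e-9, W = 30), 0, tolerance = 1e-6)
  expect_identical(builtin_model("LxW")$a, 0.42)
  expect_error(builtin_model("model9"), "no built-in model")
})

test_that("fitting workflow screens, fits and selects on records", {
  pop <- generate_population(111, noise_sd = 0.05, seed = 77)
  res <- fit_allometric_models(pop, kinds = c("L", "W", "L+W", "LxW"))
  expect_identical(res$best$kind, "LxW")
  expect_equal(res$best$a, 0.42, tolerance = 0.02)
  expect_gt(res$best$R2, 0.98)
  expect_named(res$models, c("L", "W", "L+W", "LxW"))
})

test_that("models serialize to JSON and back", {
  m <- fit_through_origin(c(1, 2, 3), c(2.1, 3.9, 6.2), kind = "LxW")
  tmp <- tempfile(fileext = ".json")
  write_model_json(m, tmp)
  back <- read_model_json(tmp)
  expect_equal(back$a, m$a)
  expect_identical(back$kind, m$kind)
  expect_equal(back$RMSE, m$RMSE)
})
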