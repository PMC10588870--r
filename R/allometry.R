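# Allometric leaf-area models: length-width predictors, correlation
# screening, least-squares fits through the origin (LA = a * x), model
# selection, and prediction.

PREDICTOR_KINDS <- c("L", "W", "L+W", "LxW", "L/W")

normalize_kind <- function(kind) {
  k <- gsub("\\s", "", kind)
  k[k %in% c("L*W", "LW", "LxW")] <- "LxW"
  if (!all(k %in% PREDICTOR_KINDS))
    stop("unknown predictor kind: ", paste(setdiff(k, PREDICTOR_KINDS), collapse = ", "))
  k
}

#' Build an allometric predictor from leaf descriptors
#'
#' @param L,W leaf length and width, cm (vectorized).
#' @param kind one of `"L"`, `"W"`, `"L+W"`, `"LxW"` (also accepted as
#'   `"L*W"`), `"L/W"`.
#' @return predictor values.
#' @export
build_predictor <- function(L, W, kind) {
  kind <- normalize_kind(kind)
  if (any(L <= 0) || any(W <= 0)) stop("L and W must be positive")
  switch(kind,
         "L" = L, "W" = W, "L+W" = L + W, "LxW" = L * W, "L/W" = L / W)
}

#' Screen a predictor by correlation with measured leaf area
#'
#' Pearson correlation t-test; a predictor fails the screen when its
#' p-value exceeds `alpha` (this is how ratio predictors such as L/W are
#' excluded before model fitting).
#'
#' @param x predictor values.
#' @param la measured leaf areas, cm^2.
#' @param alpha significance level (default 0.01).
#' @return list with `pass`, `p_value` and `r`.
#' @export
screen_predictor <- function(x, la, alpha = 0.01) {
  stopifnot(length(x) == length(la), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(la) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- stats::cor.test(x, la, method = "pearson")
  list(pass = ct$p.value <= alpha, p_value = ct$p.value,
       r = unname(ct$estimate))
}

#' Fit a linear leaf-area model through the origin
#'
#' Least squares for `la = a * x` with no intercept:
#' `a = sum(x * la) / sum(x^2)`.  `RMSE` uses the `1/n` denominator.  The
#' default `R2` is the squared Pearson correlation between observed and
#' fitted values, which is bounded in [0, 1] and comparable across
#' models; the uncentered variant `1 - SSE / sum(la^2)` is available
#' because centered R2 is ill-behaved for no-intercept fits.
#'
#' @param x predictor values.
#' @param la measured leaf areas, cm^2.
#' @param kind predictor kind label stored in the model.
#' @param r2 `"correlation"` (default) or `"uncentered"`.
#' @return object of class `allometric_model`: `kind`, `a`, `n`, `R2`,
#'   `RMSE`, `r2_method`.
#' @export
fit_through_origin <- function(x, la, kind = "LxW",
                               r2 = c("correlation", "uncentered")) {
  r2 <- match.arg(r2)
  stopifnot(length(x) == length(la), length(x) >= 2)
  sxx <- sum(x^2)
  if (sxx == 0) stop("predictor is identically zero")
  a <- sum(x * la) / sxx
  fit <- a * x
  res <- la - fit
  rmse <- sqrt(mean(res^2))
  R2 <- if (r2 == "correlation") {
    if (stats::sd(fit) == 0 || stats::sd(la) == 0) NA_real_
    else stats::cor(fit, la)^2
  } else 1 - sum(res^2) / sum(la^2)
  allometric_model(kind = kind, a = a, n = length(x), R2 = R2, RMSE = rmse,
                   r2_method = r2)
}

#' Construct an allometric model object
#'
#' @param kind predictor kind (see [build_predictor()]).
#' @param a through-origin slope (area units per predictor unit).
#' @param n sample size behind the fit.
#' @param R2,RMSE fit diagnostics (may be `NA` for published models
#'   constructed from a coefficient alone).
#' @param r2_method how `R2` was defined.
#' @param provenance free-text origin of the coefficient.
#' @return object of class `allometric_model`.
#' @export
allometric_model <- function(kind, a, n = NA_integer_, R2 = NA_real_,
                             RMSE = NA_real_, r2_method = "correlation",
                             provenance = "fitted") {
  kind <- normalize_kind(kind)
  stopifnot(is.finite(a))
  structure(list(kind = kind, a = a, n = as.integer(n), R2 = R2, RMSE = RMSE,
                 r2_method = r2_method, provenance = provenance),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("allometric model: LA = %.4g * (%s)   [n = %s, R2 = %s, RMSE = %s, %s]\n",
              x$a, x$kind,
              ifelse(is.na(x$n), "?", x$n),
              ifelse(is.na(x$R2), "?", sprintf("%.4f", x$R2)),
              ifelse(is.na(x$RMSE), "?", sprintf("%.2f", x$RMSE)),
              x$provenance))
  invisible(x)
}

#' Select the best allometric model
#'
#' Ranks by highest `R2`, ties broken by lowest `RMSE`, then by predictor
#' simplicity (`L`, `W`, `L+W`, `LxW`); deterministic.
#'
#' @param models list of [allometric_model()] objects.
#' @return the winning model.
#' @export
select_best_model <- function(models) {
  if (!length(models)) stop("no models to select from")
  simp <- match(vapply(models, `[[`, character(1), "kind"),
                c("L", "W", "L+W", "LxW", "L/W"))
  R2 <- vapply(models, `[[`, numeric(1), "R2")
  RMSE <- vapply(models, `[[`, numeric(1), "RMSE")
  ord <- order(-R2, RMSE, simp)
  models[[ord[1]]]
}

#' Predict leaf area from an allometric model
#'
#' @param model an [allometric_model()].
#' @param L,W leaf descriptors, cm (vectorized).
#' @return predicted leaf area(s), cm^2.
#' @export
predict_la <- function(model, L, W) {
  stopifnot(inherits(model, "allometric_model"))
  model$a * build_predictor(L, W, model$kind)
}

#' Fit and screen the candidate allometric models
#'
#' Builds each candidate predictor from the records, screens it by
#' correlation (screened-out predictors are excluded with a warning, the
#' fate of the L/W ratio on cassava data), fits the survivors through the
#' origin and selects the best.
#'
#' @param records leaf-record data.frame with `L`, `W`, `LA`.
#' @param kinds candidate predictor kinds.
#' @param screen apply the correlation screen.
#' @param alpha screening significance level.
#' @param r2 R2 definition, see [fit_through_origin()].
#' @return list with `models` (named list), `screened_out` (named
#'   p-values) and `best`.
#' @export
fit_allometric_models <- function(records, kinds = PREDICTOR_KINDS,
                                  screen = TRUE, alpha = 0.01,
                                  r2 = "correlation") {
  stopifnot(all(c("L", "W", "LA") %in% names(records)))
  kinds <- normalize_kind(kinds)
  models <- list(); dropped <- numeric(0)
  for (k in kinds) {
    x <- build_predictor(records$L, records$W, k)
    if (screen) {
      sc <- screen_predictor(x, records$LA, alpha = alpha)
      if (!sc$pass) {
        warning(sprintf("predictor %s screened out (p = %.3g > %g)",
                        k, sc$p_value, alpha))
        dropped[k] <- sc$p_value
        next
      }
    }
    models[[k]] <- fit_through_origin(x, records$LA, kind = k, r2 = r2)
  }
  list(models = models, screened_out = dropped,
       best = select_best_model(models))
}

# Coefficients published for cassava palmate leaves (three cultivars,
# five cultivation conditions; fitted on 111 representative leaves).
.builtin_registry <- list(
  model1 = list(kind = "L",   a = 11.58, n = 111L, R2 = 0.7221, RMSE = 44.30),
  model2 = list(kind = "W",   a = 8.54,  n = 111L, R2 = 0.6921, RMSE = 60.58),
  model3 = list(kind = "L+W", a = 4.92,  n = 111L, R2 = 0.7113, RMSE = 155.47),
  model4 = list(kind = "LxW", a = 0.42,  n = 111L, R2 = 0.9566, RMSE = 17.54)
)

#' Built-in cassava allometric models
#'
#' Published through-origin coefficients for cassava palmate leaves so
#' prediction works without refitting.  `"model4"` (`LA = 0.42 * L * W`)
#' is the recommended model; models 1-3 use `L`, `W` and `L+W`.
#'
#' @param name registry name (`"model1"`..`"model4"`) or a predictor kind.
#' @return an [allometric_model()]; or, with no argument, the names.
#' @export
builtin_model <- function(name = "model4") {
  if (missing(name)) return(names(.builtin_registry))
  nm <- tolower(name)
  if (!nm %in% names(.builtin_registry)) {
    k <- tryCatch(normalize_kind(name), error = function(e) NA_character_)
    hit <- vapply(.builtin_registry, function(m) identical(m$kind, k), logical(1))
    if (!any(hit)) stop("no built-in model named '", name, "'")
    nm <- names(.builtin_registry)[hit][1]
  }
  m <- .builtin_registry[[nm]]
  allometric_model(kind = m$kind, a = m$a, n = m$n, R2 = m$R2, RMSE = m$RMSE,
                   provenance = paste0("builtin:", nm))
}

#' Serialize / deserialize allometric models as JSON
#'
#' @param model an [allometric_model()].
#' @param path file path.
#' @return `read_model_json()` returns the model; `write_model_json()`
#'   returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "allometric_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  allometric_model(kind = m$kind, a = m$a, n = m$n %||% NA_integer_,
                   R2 = m$R2 %||% NA_real_, RMSE = m$RMSE %||% NA_real_,
                   r2_method = m$r2_method %||% "correlation",
                   provenance = m$provenance %||% "file")
}
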