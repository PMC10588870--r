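# Evaluation metrics for comparing per-plant total leaf area between an
# estimated method (M_o) and a benchmark method (M_b):
#   RMSE = sqrt(mean((M_o - M_b)^2))
#   MAE  = mean(|M_o - M_b|)
#   MRE  = mean(|M_o - M_b| / M_b)
# plus the Pearson correlation of the two vectors.

check_pair <- function(est, bench) {
  if (length(est) != length(bench)) stop("length mismatch between est and bench")
  if (!length(est)) stop("empty input")
  if (anyNA(est) || anyNA(bench)) stop("missing values in input")
  invisible(TRUE)
}

#' Root mean square error of two per-plant total-LA vectors
#'
#' @param est estimated totals (M_o).
#' @param bench benchmark totals (M_b).
#' @return RMSE in the units of the inputs.
#' @export
la_rmse <- function(est, bench) {
  check_pair(est, bench)
  sqrt(mean((est - bench)^2))
}

#' Mean absolute error
#' @inheritParams la_rmse
#' @return MAE in the units of the inputs.
#' @export
la_mae <- function(est, bench) {
  check_pair(est, bench)
  mean(abs(est - bench))
}

#' Mean relative absolute error
#'
#' Dimensionless; the benchmark is the denominator, so the orientation of
#' the arguments matters.
#'
#' @inheritParams la_rmse
#' @return MRE (dimensionless).
#' @export
la_mre <- function(est, bench) {
  check_pair(est, bench)
  if (any(bench == 0)) stop("benchmark contains zero entries; MRE undefined")
  mean(abs(est - bench) / bench)
}

#' Pearson correlation of two total-LA vectors
#'
#' @param x,y numeric vectors.
#' @return product-moment correlation.
#' @export
pearson_r <- function(x, y) {
  check_pair(x, y)
  if (length(x) < 2) stop("need at least two pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Compare two per-plant total-LA vectors
#'
#' Bundles RMSE, MAE, MRE, Pearson r and the per-plant absolute
#' residuals.  When either vector has zero variance (e.g. identical
#' inputs) the correlation is reported as `NA` with `r_defined = FALSE`.
#'
#' @param est estimated totals (M_o), a numeric vector or a data.frame
#'   with `plant_id` and a totals column.
#' @param bench benchmark totals (M_b), same form; when data.frames are
#'   given they are matched on `plant_id` and must agree.
#' @param ids optional plant identifiers for vector input.
#' @return object of class `evaluation_report`.
#' @export
evaluate_methods <- function(est, bench, ids = NULL) {
  pick_col <- function(d) {
    num <- setdiff(names(d)[vapply(d, is.numeric, logical(1))], "plant_id")
    if (!length(num)) stop("no numeric totals column found")
    d[[num[1]]]
  }
  if (is.data.frame(est) && is.data.frame(bench)) {
    if (!all(c("plant_id") %in% names(est)) || !all(c("plant_id") %in% names(bench)))
      stop("data.frame inputs need a plant_id column")
    m <- match(est$plant_id, bench$plant_id)
    if (anyNA(m) || nrow(est) != nrow(bench))
      stop("unmatched plant ids between est and bench")
    ids <- as.character(est$plant_id)
    bench <- pick_col(bench)[m]
    est <- pick_col(est)
  }
  check_pair(est, bench)
  res <- abs(est - bench)
  r_def <- length(est) >= 2 && stats::sd(est) > 0 && stats::sd(bench) > 0
  structure(list(n = length(est),
                 RMSE = la_rmse(est, bench),
                 MAE = la_mae(est, bench),
                 MRE = la_mre(est, bench),
                 r = if (r_def) stats::cor(est, bench) else NA_real_,
                 r_defined = r_def,
                 per_plant_residuals = stats::setNames(res, ids),
                 est = est, bench = bench),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("method comparison over %d plants\n", x$n))
  cat(sprintf("  RMSE = %.2f   MAE = %.2f   MRE = %.2f   r = %s\n",
              x$RMSE, x$MAE, x$MRE,
              if (x$r_defined) sprintf("%.4f", x$r) else "undefined"))
  cat("  |residuals| =", paste(sprintf("%.2f", x$per_plant_residuals),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Evaluation report as a one-row data.frame
#'
#' @param x an [evaluate_methods()] report.
#' @param ... unused.
#' @return data.frame with `n`, `RMSE`, `MAE`, `MRE`, `r`.
#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(n = x$n, RMSE = x$RMSE, MAE = x$MAE, MRE = x$MRE, r = x$r)
}
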