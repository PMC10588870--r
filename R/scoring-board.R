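# Scoring-board clustering: bin leaves into size clusters on a grid of
# nested squares, pick representatives, and aggregate per-plant totals as
#   total LA per plant = sum_i (LA_rep * LN)_i
# over the N clusters of the plant.

#' Scoring-board specification
#'
#' The physical board is a set of nested squares from `min_cell` to
#' `max_cell` inches in `step`-inch increments; a leaf is assigned to the
#' smallest square that contains its L and W footprint.
#'
#' @param min_cell,max_cell smallest and largest grid line, inches.
#' @param step grid increment, inches.
#' @param cm_per_inch unit conversion (2.54).
#' @return object of class `board_spec`.
#' @export
board_spec <- function(min_cell = 3.5, max_cell = 15.5, step = 1,
                       cm_per_inch = 2.54) {
  stopifnot(min_cell > 0, min_cell < max_cell, step > 0, cm_per_inch > 0)
  k <- (max_cell - min_cell) / step
  if (abs(k - round(k)) > 1e-8)
    stop("max_cell must be min_cell plus a whole number of steps")
  structure(list(min_cell = min_cell, max_cell = max_cell, step = step,
                 cm_per_inch = cm_per_inch,
                 lines = seq(min_cell, max_cell, by = step)),
            class = "board_spec")
}

#' @export
print.board_spec <- function(x, ...) {
  cat(sprintf("scoring board: %.1f-%.1f inch squares in %.2g-inch steps (%d lines)\n",
              x$min_cell, x$max_cell, x$step, length(x$lines)))
  invisible(x)
}

# snap cm values up to the smallest grid line >= value (inches);
# below-range values snap to the first line, above-range to Inf (overflow)
snap_to_board <- function(values_cm, board) {
  v <- values_cm / board$cm_per_inch
  cnt <- findInterval(v, board$lines)
  on_line <- cnt >= 1 & abs(v - board$lines[pmax(cnt, 1L)]) < 1e-9
  idx <- ifelse(on_line, cnt, cnt + 1L)
  ifelse(idx > length(board$lines), Inf, board$lines[pmin(idx, length(board$lines))])
}

fmt_cell <- function(cell, board) {
  ifelse(is.finite(cell), sprintf("%.1f", cell), paste0(">", board$max_cell))
}

#' Assign leaves to scoring-board clusters
#'
#' Each dimension is converted to inches and rounded up to the smallest
#' grid line that contains it (values exactly on a line belong to that
#' line); values below the smallest square map to it, and values beyond
#' the largest square map to a flagged overflow cell.
#'
#' @param L,W leaf length and width, cm (vectorized).
#' @param board a [board_spec()].
#' @return data.frame with `L_cell`, `W_cell` (inches, `Inf` = overflow),
#'   `overflow` flag and the cluster `key` string.
#' @export
assign_cluster <- function(L, W, board = board_spec()) {
  stopifnot(inherits(board, "board_spec"))
  if (any(!is.finite(L)) || any(!is.finite(W)) || any(L <= 0) || any(W <= 0))
    stop("leaf dimensions must be positive finite numbers")
  lc <- snap_to_board(L, board)
  wc <- snap_to_board(W, board)
  data.frame(L_cell = lc, W_cell = wc,
             overflow = !is.finite(lc) | !is.finite(wc),
             key = paste(fmt_cell(lc, board), fmt_cell(wc, board), sep = "x"),
             stringsAsFactors = FALSE)
}

#' Group one plant's leaves into size clusters
#'
#' Partitions the leaves of a single plant over the scoring-board cells:
#' every leaf belongs to exactly one cluster and cluster sizes sum to the
#' leaf count.
#'
#' @param records leaf-record data.frame (columns `plant_id`, `leaf_id`,
#'   `L`, `W`, optionally `LA`) for one plant.
#' @param board a [board_spec()].
#' @return object of class `leaf_clusters`: a data.frame with one row per
#'   occupied cell (`plant_id`, `key`, `L_cell`, `W_cell`, `overflow`,
#'   `LN`, list column `member_ids`, `rep_ids`, `la_rep`), with the board
#'   attached as an attribute.
#' @export
group_leaves <- function(records, board = board_spec()) {
  if (is.null(records) || !nrow(records)) stop("no leaves to cluster")
  stopifnot(all(c("plant_id", "leaf_id", "L", "W") %in% names(records)))
  if (length(unique(records$plant_id)) != 1L)
    stop("group_leaves() expects the leaves of a single plant")
  asg <- assign_cluster(records$L, records$W, board)
  sp <- split(seq_len(nrow(records)), asg$key)
  cl <- data.frame(plant_id = records$plant_id[1],
                   key = names(sp), stringsAsFactors = FALSE)
  first <- vapply(sp, `[`, integer(1), 1L)
  cl$L_cell <- asg$L_cell[first]
  cl$W_cell <- asg$W_cell[first]
  cl$overflow <- asg$overflow[first]
  cl$LN <- vapply(sp, length, integer(1))
  cl$member_ids <- I(lapply(sp, function(i) records$leaf_id[i]))
  cl$rep_ids <- I(vector("list", nrow(cl)))
  cl$la_rep <- NA_real_
  cl <- cl[order(cl$L_cell, cl$W_cell), ]
  rownames(cl) <- NULL
  attr(cl, "board") <- board
  class(cl) <- c("leaf_clusters", class(cl))
  cl
}

#' Randomly select representative leaves per cluster
#'
#' Samples `min(k, LN)` members uniformly without replacement in each
#' cluster under the stated seed (recorded in the result's attributes for
#' reproducibility).
#'
#' @param clusters a [group_leaves()] result.
#' @param k representatives per cluster (default 2, "a couple").
#' @param seed integer seed (mandatory).
#' @return `clusters` with `rep_ids` filled.
#' @export
select_representatives <- function(clusters, k = 2L, seed) {
  stopifnot(inherits(clusters, "leaf_clusters"), k >= 1)
  clusters$rep_ids <- I(with_seed(as.integer(seed), {
    lapply(clusters$member_ids, function(ids) {
      if (length(ids) <= k) ids else sample(ids, k)
    })
  }))
  attr(clusters, "rep_seed") <- as.integer(seed)
  attr(clusters, "rep_k") <- as.integer(k)
  clusters
}

#' Set each cluster's representative leaf area
#'
#' `LA_rep` is the arithmetic mean over the cluster's representatives of
#' either their measured `LA` (photographic workflow) or, when an
#' allometric `model` is supplied, the model prediction from their
#' measured `L` and `W` (hybrid workflow).
#'
#' @param clusters a [select_representatives()] result.
#' @param records the plant's leaf records (source of `LA`, `L`, `W`).
#' @param model optional [allometric model][fit_through_origin()].
#' @return `clusters` with `la_rep` filled.
#' @export
set_representative_area <- function(clusters, records, model = NULL) {
  stopifnot(inherits(clusters, "leaf_clusters"))
  if (any(!vapply(clusters$rep_ids, length, integer(1))))
    stop("representatives not selected; call select_representatives() first")
  la_of <- function(ids) {
    i <- match(ids, records$leaf_id)
    if (anyNA(i)) stop("representative ids missing from records")
    if (is.null(model)) {
      if (!"LA" %in% names(records) || anyNA(records$LA[i]))
        stop("measured LA missing for representatives; supply a model or LA values")
      records$LA[i]
    } else {
      predict_la(model, L = records$L[i], W = records$W[i])
    }
  }
  clusters$la_rep <- vapply(clusters$rep_ids, function(ids) mean(la_of(ids)),
                            numeric(1))
  clusters
}

#' Per-plant total leaf area over clusters
#'
#' Total LA per plant is the sum over the plant's clusters of the
#' representative area times the cluster leaf count.
#'
#' @param clusters a [leaf_clusters][group_leaves()] data.frame with
#'   `la_rep` set.
#' @return one-row data.frame: `plant_id`, `n_clusters`, `n_leaves`,
#'   `total_la_cm2`, `total_la_m2`.
#' @export
total_leaf_area <- function(clusters) {
  stopifnot(inherits(clusters, "leaf_clusters"))
  if (anyNA(clusters$la_rep))
    stop("cluster(s) missing la_rep; call set_representative_area() first")
  data.frame(plant_id = clusters$plant_id[1],
             n_clusters = nrow(clusters),
             n_leaves = sum(clusters$LN),
             total_la_cm2 = sum(clusters$la_rep * clusters$LN),
             total_la_m2 = sum(clusters$la_rep * clusters$LN) / 1e4,
             stringsAsFactors = FALSE)
}

#' Estimate per-plant total leaf area from leaf records
#'
#' One-shot estimator covering both workflows.  `mode = "photo"` uses the
#' measured `LA` of the sampled representatives.  `mode = "hybrid"`
#' predicts representative areas from an allometric model, either from
#' the representatives' measured `L`/`W` (`hybrid_from =
#' "representatives"`, default) or from the cluster cell dimensions
#' themselves (`hybrid_from = "cells"`, the datasheet-only field workflow
#' needing no per-leaf measurement; overflow cells are not allowed there).
#'
#' @param records leaf-record data.frame, possibly several plants.
#' @param board a [board_spec()].
#' @param mode `"photo"` or `"hybrid"`.
#' @param model allometric model (required for `"hybrid"`).
#' @param k representatives per cluster.
#' @param seed integer seed for representative sampling.
#' @param hybrid_from `"representatives"` or `"cells"`.
#' @return data.frame with one row per plant (see [total_leaf_area()]).
#' @export
estimate_total_la <- function(records, board = board_spec(),
                              mode = c("photo", "hybrid"), model = NULL,
                              k = 2L, seed = 1L,
                              hybrid_from = c("representatives", "cells")) {
  mode <- match.arg(mode)
  hybrid_from <- match.arg(hybrid_from)
  if (mode == "hybrid" && is.null(model))
    stop("hybrid estimation requires an allometric model")
  out <- lapply(split(records, records$plant_id), function(rec) {
    cl <- group_leaves(rec, board)
    cl <- select_representatives(cl, k = k, seed = seed)
    if (mode == "hybrid" && hybrid_from == "cells") {
      if (any(cl$overflow))
        stop("cell-based hybrid estimation cannot handle overflow cells")
      Lc <- cl$L_cell * board$cm_per_inch
      Wc <- cl$W_cell * board$cm_per_inch
      cl$la_rep <- predict_la(model, L = Lc, W = Wc)
    } else {
      cl <- set_representative_area(cl, rec,
                                    model = if (mode == "hybrid") model)
    }
    total_leaf_area(cl)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$plant_id), , drop = FALSE]
}
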