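# Canonical CSV schemas: leaf records, cluster datasheets and per-plant
# totals.  Comma-separated, UTF-8, header row, "." decimal; lengths in cm
# and areas in cm^2 throughout (inches exist only inside the board spec).

LEAF_RECORD_COLS <- c("plant_id", "leaf_id", "L", "W", "LA",
                      "cluster_key", "is_representative", "source")

canonical_records <- function(records) {
  for (col in LEAF_RECORD_COLS)
    if (!col %in% names(records))
      records[[col]] <- switch(col,
                               LA = NA_real_,
                               cluster_key = NA_character_,
                               is_representative = FALSE,
                               source = "manual",
                               stop("missing required column: ", col))
  records[LEAF_RECORD_COLS]
}

#' Read a leaf-record table
#'
#' Requires columns `plant_id`, `leaf_id`, `L`, `W`; `LA`,
#' `cluster_key`, `is_representative` and `source` are optional and
#' filled with defaults.  Malformed rows (non-positive or non-numeric
#' dimensions, non-positive `LA`) are reported with their line numbers.
#'
#' @param path CSV file.
#' @return leaf-record data.frame in canonical column order.
#' @export
read_leaf_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "leaf_id", "L", "W")
  if (!all(need %in% names(d)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d$L <- suppressWarnings(as.numeric(d$L))
  d$W <- suppressWarnings(as.numeric(d$W))
  if ("LA" %in% names(d)) d$LA <- suppressWarnings(as.numeric(d$LA))
  bad <- !is.finite(d$L) | !is.finite(d$W) | d$L <= 0 | d$W <= 0
  if ("LA" %in% names(d))
    bad <- bad | (!is.na(d$LA) & d$LA <= 0)
  if (any(bad))
    stop("malformed leaf record(s) at line(s) ",
         paste(which(bad) + 1L, collapse = ", "),
         " of ", path, " (dimensions must be positive numbers)")
  canonical_records(d)
}

#' Write a leaf-record table
#'
#' @param records leaf-record data.frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_leaf_table <- function(records, path) {
  utils::write.csv(canonical_records(records), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a cluster datasheet
#'
#' Mirrors the field record sheet: one row per cluster with the cell key,
#' cell dimensions (inches and cm), leaf count, representative ids and
#' representative area.
#'
#' @param clusters a [group_leaves()] result.
#' @param path CSV file.
#' @return `path` invisibly; `read_cluster_sheet()` returns a data.frame.
#' @export
write_cluster_sheet <- function(clusters, path) {
  board <- attr(clusters, "board") %||% board_spec()
  d <- data.frame(plant_id = clusters$plant_id,
                  cluster_key = clusters$key,
                  L_cell_in = clusters$L_cell,
                  W_cell_in = clusters$W_cell,
                  L_cell_cm = clusters$L_cell * board$cm_per_inch,
                  W_cell_cm = clusters$W_cell * board$cm_per_inch,
                  leaf_count = clusters$LN,
                  representative_ids = vapply(clusters$rep_ids, paste,
                                              character(1), collapse = ";"),
                  la_rep_cm2 = clusters$la_rep,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cluster_sheet
#' @export
read_cluster_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read per-plant totals
#'
#' @param totals data.frame from [estimate_total_la()] (or with at least
#'   `plant_id` and one totals column).
#' @param path CSV file.
#' @return `path` invisibly; `read_totals_table()` returns a data.frame.
#' @export
write_totals_table <- function(totals, path) {
  utils::write.csv(totals, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_totals_table
#' @export
read_totals_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"plant_id" %in% names(d)) stop("totals table needs a plant_id column")
  d
}

#' Published per-plant total leaf-area benchmarks for cassava
#'
#' Two reference tables of per-plant totals for cassava, shipped as
#' plain-text fixtures.  `"field"`: nine field-grown plants (1,821 leaves)
#' measured by three methods — photographic with clustering (`m1`), leaf
#' area meter with clustering (`m2`), and leaf area meter without
#' clustering (`m3`).  `"greenhouse"`: six greenhouse-grown plants
#' (78 leaves) by the hybrid estimator (`hybrid`) and the photographic
#' method (`photo`).  Totals are reported as printed, treated as given
#' unit-free numbers.
#'
#' @param dataset `"field"` or `"greenhouse"`.
#' @return data.frame of per-plant totals.
#' @export
reference_totals <- function(dataset = c("field", "greenhouse")) {
  dataset <- match.arg(dataset)
  f <- switch(dataset,
              field = "field_totals_three_methods.csv",
              greenhouse = "greenhouse_totals_hybrid_photo.csv")
  utils::read.csv(system.file("extdata", f, package = "palmleaf",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
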