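# Pipeline orchestration: measurement -> clustering -> fitting ->
# estimation -> evaluation, each step reading and writing the canonical
# CSV schemas so runs are scriptable and replayable.

# write a replayable run log (config hash, seed, package version)
write_run_log <- function(out_dir, step, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  log <- list(step = step, config = config, config_md5 = hash,
              package = "palmleaf",
              version = as.character(utils::packageVersion("palmleaf")),
              r_version = R.version.string,
              time = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, paste0(step, ".log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(hash)
}

#' Measure every leaf photograph in a directory
#'
#' Segments and measures each image (PNG/TIFF/JPEG), writing one leaf
#' record per image.  The plant and leaf identity are taken from the file
#' name `<plant>_<leaf>.<ext>` (a name without an underscore becomes a
#' single-plant record).
#'
#' @param image_dir directory of single-leaf photographs.
#' @param out_dir output directory.
#' @param ppcm pixels per centimeter; alternatively `marker_cm` to
#'   calibrate each image from a square fiducial of that side.
#' @param marker_cm fiducial side, cm (used when `ppcm` is NULL).
#' @param method descriptor algorithm, see [measure_descriptors()].
#' @param ... passed to [segment_leaf()].
#' @return path of the written leaf-record CSV, invisibly.
#' @export
pipeline_measure <- function(image_dir, out_dir, ppcm = NULL,
                             marker_cm = NULL, method = "tip-based", ...) {
  files <- sort(list.files(image_dir, pattern = "\\.(png|tif|tiff|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no images found in ", image_dir)
  if (is.null(ppcm) && is.null(marker_cm))
    stop("supply either ppcm or marker_cm")
  rows <- lapply(files, function(f) {
    img <- read_leaf_image(f, ppcm = ppcm)
    if (is.null(ppcm)) img$ppcm <- calibrate_scale(img, marker_cm)
    m <- measure_leaf(img, method = method, ...)
    id <- sub("\\.[^.]+$", "", basename(f))
    parts <- strsplit(id, "_", fixed = TRUE)[[1]]
    data.frame(plant_id = if (length(parts) > 1) parts[1] else "plant1",
               leaf_id = id, L = m$L, W = m$W, LA = m$LA,
               cluster_key = NA_character_, is_representative = FALSE,
               source = "image", stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, "leaf_records.csv")
  write_leaf_table(records, out)
  write_run_log(out_dir, "measure",
                list(image_dir = image_dir, n_images = length(files),
                     ppcm = ppcm, marker_cm = marker_cm, method = method))
  invisible(out)
}

#' Cluster measured leaves on the scoring board
#'
#' @param records_csv leaf-record CSV.
#' @param out_dir output directory.
#' @param board a [board_spec()].
#' @param k representatives per cluster.
#' @param seed sampling seed.
#' @return paths of the written per-plant cluster datasheets, invisibly.
#' @export
pipeline_cluster <- function(records_csv, out_dir, board = board_spec(),
                             k = 2L, seed = 1L) {
  records <- read_leaf_table(records_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(records, records$plant_id), function(rec) {
    cl <- group_leaves(rec, board)
    cl <- select_representatives(cl, k = k, seed = seed)
    if (!anyNA(rec$LA)) cl <- set_representative_area(cl, rec)
    p <- file.path(out_dir, paste0("clusters_", rec$plant_id[1], ".csv"))
    write_cluster_sheet(cl, p)
    p
  }, character(1))
  write_run_log(out_dir, "cluster",
                list(records = records_csv, k = k, seed = seed,
                     board = unclass(board)[c("min_cell", "max_cell", "step")]))
  invisible(unname(paths))
}

#' Fit allometric models from measured records
#'
#' @param records_csv leaf-record CSV with measured `LA`.
#' @param out_dir output directory.
#' @param predictor `"auto"` (screen all candidates and keep the best) or
#'   a single predictor kind.
#' @return path of the written model JSON, invisibly.
#' @export
pipeline_fit <- function(records_csv, out_dir, predictor = "auto") {
  records <- read_leaf_table(records_csv)
  if (anyNA(records$LA)) stop("fitting requires measured LA for every record")
  model <- if (identical(predictor, "auto")) {
    fit_allometric_models(records)$best
  } else {
    k <- normalize_kind(predictor)
    fit_through_origin(build_predictor(records$L, records$W, k),
                       records$LA, kind = k)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, "model.json")
  write_model_json(model, out)
  write_run_log(out_dir, "fit",
                list(records = records_csv, predictor = predictor,
                     kind = model$kind, a = model$a))
  invisible(out)
}

#' Estimate per-plant totals from records
#'
#' @param records_csv leaf-record CSV.
#' @param out_dir output directory.
#' @param mode `"photo"` (measured representative areas) or `"hybrid"`
#'   (model-predicted representative areas).
#' @param model `"builtin:model4"`-style registry reference, a model JSON
#'   path, or an [allometric_model()].
#' @param board a [board_spec()].
#' @param k,seed representative sampling parameters.
#' @param hybrid_from see [estimate_total_la()].
#' @return path of the written totals CSV, invisibly.
#' @export
pipeline_estimate <- function(records_csv, out_dir, mode = "photo",
                              model = "builtin:model4", board = board_spec(),
                              k = 2L, seed = 1L,
                              hybrid_from = "representatives") {
  records <- read_leaf_table(records_csv)
  mdl <- NULL
  if (mode == "hybrid") {
    mdl <- if (inherits(model, "allometric_model")) model
    else if (is.character(model) && startsWith(model, "builtin:"))
      builtin_model(sub("^builtin:", "", model))
    else read_model_json(model)
  }
  totals <- estimate_total_la(records, board = board, mode = mode,
                              model = mdl, k = k, seed = seed,
                              hybrid_from = hybrid_from)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, paste0("totals_", mode, ".csv"))
  write_totals_table(totals, out)
  write_run_log(out_dir, "estimate",
                list(records = records_csv, mode = mode, k = k, seed = seed,
                     model = if (!is.null(mdl)) mdl[c("kind", "a")],
                     hybrid_from = hybrid_from))
  invisible(out)
}

#' Evaluate two per-plant totals tables
#'
#' @param est_csv,bench_csv totals CSVs (matched on `plant_id`; the
#'   benchmark is the MRE denominator).
#' @param out_dir output directory.
#' @return the [evaluate_methods()] report, invisibly; a CSV summary and
#'   residual table are written to `out_dir`.
#' @export
pipeline_evaluate <- function(est_csv, bench_csv, out_dir) {
  est <- read_totals_table(est_csv)
  bench <- read_totals_table(bench_csv)
  rep <- evaluate_methods(est, bench)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(rep),
                   file.path(out_dir, "evaluation_summary.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(data.frame(plant_id = names(rep$per_plant_residuals),
                              est = rep$est, bench = rep$bench,
                              abs_residual = unname(rep$per_plant_residuals)),
                   file.path(out_dir, "evaluation_residuals.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  write_run_log(out_dir, "evaluate",
                list(est = est_csv, bench = bench_csv))
  invisible(rep)
}

#' Simulate a plant's leaves as scenes with ground truth
#'
#' Renders each synthetic leaf as a PNG scene and writes the ground-truth
#' leaf records (`LA` = polygon area) alongside.
#'
#' @param out_dir output directory (scenes under `scenes/`).
#' @param n_leaves leaves to simulate.
#' @param seed integer seed.
#' @param ppcm rendering scale.
#' @param plant_id plant identifier.
#' @param render write PNG scenes (set FALSE for records only).
#' @return list with `records_csv`, `scene_dir`, and the `truths`,
#'   invisibly.
#' @export
pipeline_simulate <- function(out_dir, n_leaves = 50L, seed = 1L, ppcm = 20,
                              plant_id = "plant1", render = TRUE) {
  sim <- simulate_plant(n_leaves, seed = seed, plant_id = plant_id)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scene_dir <- file.path(out_dir, "scenes")
  if (render) {
    dir.create(scene_dir, showWarnings = FALSE)
    for (i in seq_len(n_leaves)) {
      img <- render_leaf(sim$truths[[i]], ppcm = ppcm)
      write_image_png(img, file.path(scene_dir,
                                     paste0(sim$records$leaf_id[i], ".png")))
    }
  }
  records_csv <- file.path(out_dir, "ground_truth_records.csv")
  write_leaf_table(sim$records, records_csv)
  write_run_log(out_dir, "simulate",
                list(n_leaves = n_leaves, seed = seed, ppcm = ppcm,
                     plant_id = plant_id, render = render))
  invisible(list(records_csv = records_csv, scene_dir = scene_dir,
                 truths = sim$truths))
}
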