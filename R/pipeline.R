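# Orchestration: segment -> features -> summarize (-> compare/morphospace),
# with a JSON run manifest for reproducibility.

ts_schema_table <- function(ts_list) {
  rows <- lapply(ts_list, function(ts) {
    fr <- data.table::copy(ts$frames)
    fr[, cell_id := ts$cell_id]
    dac <- rep(NA_real_, nrow(fr))
    if (!is.null(ts$dac)) dac[seq_along(ts$dac)] <- as.numeric(ts$dac)
    fr[, dac_um2 := dac]
    fr[, fixed_area_um2 := ts$fixed$fixed_area_um2]
    data.table::setcolorder(fr, c("cell_id", "frame", "time_s"))
    fr
  })
  data.table::rbindlist(rows)
}

# Segment one probability movie into a label movie.
segment_movie <- function(prob_movie, config = pipeline_config(),
                          curation = NULL, global_threshold = FALSE) {
  bin <- binarize_movie(prob_movie, global = global_threshold)
  cleaned <- clean_binary_movie(bin, config)
  seeds <- seed_labels(cleaned, config)
  labs <- label_cells(cleaned, seeds, config, prob_movie = prob_movie)
  cur <- curate_labels(labs, seeds, curation %||% list())
  list(labels = cur$movie, seeds = cur$seeds,
       border_labels = cur$border_labels)
}

#' Run the full pipeline on one probability-map movie
#'
#' Stages: segmentation/labeling, per-cell feature time series, summary
#' quantifiers. Outputs are plain files (TIFF/CSV) plus a JSON manifest
#' capturing the configuration, input hash, seed and per-stage object
#' counts. If the output directory already holds a manifest whose input
#' hash and configuration match, the run is resumed (outputs are reused).
#'
#' @param input path to a multi-page TIFF probability movie, or a
#'   [movie()] object.
#' @param out_dir output directory (created if needed).
#' @param calibration a [calibration()]; required when `input` is a path.
#' @param config a [pipeline_config()].
#' @param curation optional curation spec (list or path to a JSON file
#'   like `{"merge": [[2, 3]], "exclude": [7]}`).
#' @param condition,experiment labels attached to the summary rows.
#' @return List with paths of the written outputs and the in-memory
#'   results (`labels`, `timeseries`, `population`, `manifest`).
#' @export
run_pipeline <- function(input, out_dir, calibration = NULL,
                         config = pipeline_config(), curation = NULL,
                         condition = "default", experiment = "exp1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(curation)) curation <- read_curation(curation)
  if (is.character(input)) {
    if (!file.exists(input)) stop("corrupt or missing input: ", input)
    if (is.null(calibration)) stop("calibration is required for file input")
    input_hash <- unname(tools::md5sum(input))
    prob <- tryCatch(read_movie(input, calibration, kind = "probability"),
                     error = function(e)
                       stop("failed to read '", input, "': ",
                            conditionMessage(e)))
  } else {
    stopifnot(inherits(input, "morphodyn_movie"))
    prob <- input
    input_hash <- digest_movie(prob)
  }
  paths <- list(labels = file.path(out_dir, "labels.tif"),
                timeseries = file.path(out_dir, "timeseries.csv"),
                summary = file.path(out_dir, "summary.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  cfg_snapshot <- unclass(config)
  manifest_new <- list(package = "morphodyn",
                       version = as.character(utils::packageVersion("morphodyn")),
                       input_hash = input_hash,
                       config = cfg_snapshot,
                       calibration = unclass(movie_cal(prob)),
                       seed = config$rng_seed,
                       curation = curation %||% list(),
                       condition = condition, experiment = experiment)
  if (file.exists(paths$manifest) && all(file.exists(unlist(paths)))) {
    old <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
    if (identical(old$input_hash, input_hash) &&
        identical(unname(unlist(old$config)),
                  unname(unlist(cfg_snapshot)))) {
      md_log("pipeline", "manifest matches: resuming from existing outputs")
      return(list(paths = paths, resumed = TRUE,
                  population = read_table(paths$summary),
                  manifest = old))
    }
  }
  seg <- tryCatch(segment_movie(prob, config, curation),
                  error = function(e)
                    stop("stage 'segment' failed: ", conditionMessage(e)))
  write_movie(seg$labels, paths$labels)
  cells <- extract_cell_movies(seg$labels)
  ts_list <- lapply(cells, function(cm)
    tryCatch(feature_timeseries(cm, config),
             error = function(e)
               stop("stage 'features' failed for cell ",
                    attr(cm, "cell_id"), ": ", conditionMessage(e))))
  tab <- ts_schema_table(ts_list)
  write_table(tab, paths$timeseries)
  usable <- Filter(function(ts) isTRUE(ts$usable), ts_list)
  summaries <- lapply(usable, function(ts)
    tryCatch(summarize_cell(ts, config), error = function(e) NULL))
  kept <- !vapply(summaries, is.null, logical(1))
  pop <- build_population(summaries[kept], condition = condition,
                          experiment = experiment,
                          cell_id = vapply(usable[kept], `[[`, integer(1),
                                           "cell_id"))
  write_table(pop, paths$summary)
  manifest_new$counts <- list(n_seeds = length(seg$seeds$areas_um2),
                              n_cells = length(cells),
                              n_usable = sum(kept),
                              border_labels = seg$border_labels)
  jsonlite::write_json(manifest_new, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  md_log("pipeline", "%d cell(s) labeled, %d summarised",
         length(cells), sum(kept))
  list(paths = paths, resumed = FALSE, labels = seg$labels,
       timeseries = tab, population = pop, manifest = manifest_new)
}

read_curation <- function(path) {
  if (!file.exists(path)) stop("no such curation file: ", path)
  sp <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(merge = lapply(sp$merge %||% list(), as.integer),
       exclude = as.integer(sp$exclude %||% integer(0)))
}

# Content hash of an in-memory movie (used in manifests).
digest_movie <- function(m) {
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  write_movie(m, tmp)
  unname(tools::md5sum(tmp))
}
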