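# Collapse per-cell time series into the 31 morphodynamic quantifiers.

TS_FEATURES <- c("area", "perimeter", "solidity", "convexity", "circularity",
                 "aspect_ratio", "angularity", "max_protrusion_length",
                 "protrusiveness")

TS_COLUMNS <- c(area = "area_um2", perimeter = "perimeter_um",
                solidity = "solidity", convexity = "convexity",
                circularity = "circularity", aspect_ratio = "aspect_ratio",
                angularity = "angularity",
                max_protrusion_length = "max_protrusion_um",
                protrusiveness = "protrusiveness")

#' Canonical names of the 31 morphodynamic quantifiers
#'
#' For each of the nine time-series features (area, perimeter, solidity,
#' convexity, circularity, aspect ratio, angularity, maximum protrusion
#' length, protrusiveness): the mean, the standard deviation normalised by
#' the mean (`var_*`), and the least-squares trend slope per second
#' (`trend_*`); plus the fixed area, the mean mobile area, the
#' mobile/fixed area ratio, and the slope of the cumulative DAC sum.
#'
#' @return Character vector of length 31, in canonical column order.
#' @export
summary_quantifier_names <- function() {
  c(unlist(lapply(TS_FEATURES, function(f)
      paste(c("mean", "var", "trend"), f, sep = "_")), use.names = FALSE),
    "fixed_area", "mean_mobile_area", "ratio_mobile_fixed",
    "dac_cumsum_slope")
}

ols_slope <- function(y, t) {
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom == 0) return(NA_real_)
  sum(tc * (y - mean(y))) / denom
}

# Shared core: compute the 31 quantifiers from a per-frame table plus the
# fixed area and DAC series. `fr` needs time_s, the nine feature columns
# and mobile_area_um2.
summary_from_parts <- function(fr, fixed_area, dac, frame_interval_s,
                               config) {
  out <- numeric(0)
  for (f in TS_FEATURES) {
    y <- fr[[TS_COLUMNS[[f]]]]
    m <- mean(y)
    s <- stats::sd(y)
    v <- if (config$raw_sd) s
         else if (s == 0) 0
         else if (m == 0) NA_real_
         else s / abs(m)
    out <- c(out, m, v, ols_slope(y, fr$time_s))
  }
  mean_mobile <- mean(fr$mobile_area_um2)
  if (is.na(fixed_area) || fixed_area <= 0)
    stop("zero fixed area: mobile/fixed ratio undefined, cell excluded")
  dac_t <- (seq_along(dac) - 1) * frame_interval_s
  out <- c(out, fixed_area, mean_mobile, mean_mobile / fixed_area,
           ols_slope(cumsum(dac), dac_t))
  names(out) <- summary_quantifier_names()
  out
}

#' Summarise one cell's time series into 31 quantifiers
#'
#' Means are arithmetic; `var_*` is the sample standard deviation (n - 1)
#' divided by the absolute mean (0 when both mean and SD are 0; raw SD
#' with `config$raw_sd = TRUE`); `trend_*` is the ordinary least-squares
#' slope against time in seconds; `ratio_mobile_fixed` is the mean mobile
#' area over the fixed area; `dac_cumsum_slope` is the OLS slope of the
#' cumulative DAC sum against time.
#'
#' @param ts a [feature_timeseries()] result with at least 3 usable frames.
#' @param config a [pipeline_config()].
#' @return Named numeric vector of length 31 (see
#'   [summary_quantifier_names()]).
#' @export
summarize_cell <- function(ts, config = pipeline_config()) {
  stopifnot(inherits(ts, "morphodyn_timeseries"))
  if (!isTRUE(ts$usable))
    stop("cell ", ts$cell_id,
         " is flagged (empty frames or empty fixed mask) and cannot be summarised")
  fr <- ts$frames
  if (nrow(fr) < 3) stop("summarize_cell requires at least 3 frames")
  summary_from_parts(fr, ts$fixed$fixed_area_um2, as.numeric(ts$dac),
                     ts$calibration$frame_interval_s, config)
}

#' Summarise every cell in a long per-frame feature table
#'
#' Works from the CSV schema written by the pipeline's feature stage
#' (columns `cell_id`, `frame`, `time_s`, the nine features,
#' `mobile_area_um2`, `dac_um2` with an empty lagged tail, and the
#' per-cell constant `fixed_area_um2`). Cells with undefined frames are
#' excluded with a report.
#'
#' @param tab a `data.frame`/`data.table` in the long feature schema.
#' @param config a [pipeline_config()].
#' @return A list with `summaries` (named list of 31-entry vectors) and
#'   `excluded` (cell ids dropped, with reasons).
#' @export
summarize_table <- function(tab, config = pipeline_config()) {
  tab <- data.table::as.data.table(tab)
  need <- c("cell_id", "time_s", unname(TS_COLUMNS), "mobile_area_um2",
            "dac_um2", "fixed_area_um2")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  summaries <- list()
  excluded <- character(0)
  for (id in unique(tab$cell_id)) {
    fr <- tab[tab$cell_id == id, ]
    fr <- fr[order(fr$time_s), ]
    res <- tryCatch({
      feat_cols <- c(unname(TS_COLUMNS), "mobile_area_um2")
      if (anyNA(fr[, feat_cols, with = FALSE]))
        stop("undefined frames")
      if (nrow(fr) < 3) stop("fewer than 3 frames")
      dt_s <- stats::median(diff(fr$time_s))
      summary_from_parts(fr, fr$fixed_area_um2[1],
                         fr$dac_um2[!is.na(fr$dac_um2)], dt_s, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, stats::setNames(conditionMessage(res),
                                              as.character(id)))
      md_log("summarize", "cell %s excluded: %s", id, conditionMessage(res))
    } else summaries[[as.character(id)]] <- res
  }
  list(summaries = summaries, excluded = excluded)
}

#' Assemble summary vectors into a population matrix
#'
#' @param summaries list of 31-entry vectors from [summarize_cell()], or a
#'   matrix with 31 columns.
#' @param condition condition label per cell (recycled if length 1).
#' @param experiment experiment id per cell (recycled if length 1).
#' @param cell_id cell identifiers; defaults to `seq_along(summaries)`.
#' @return A `data.table` with columns `cell_id`, `condition`,
#'   `experiment`, then the 31 quantifiers in canonical order.
#' @export
build_population <- function(summaries, condition = "default",
                             experiment = "exp1", cell_id = NULL) {
  qn <- summary_quantifier_names()
  if (is.list(summaries)) {
    if (!length(summaries)) {
      empty <- c(list(cell_id = character(0), condition = character(0),
                      experiment = character(0)),
                 stats::setNames(rep(list(numeric(0)), length(qn)), qn))
      return(data.table::as.data.table(empty))
    }
    mat <- do.call(rbind, summaries)
  } else mat <- as.matrix(summaries)
  if (ncol(mat) != length(qn) || is.null(colnames(mat)) ||
      !all(colnames(mat) == qn))
    stop("summaries must carry the 31 canonical quantifiers in order")
  if (anyNA(mat)) stop("population matrix must not contain undefined entries")
  n <- nrow(mat)
  if (is.null(cell_id)) cell_id <- as.character(seq_len(n))
  if (anyDuplicated(cell_id)) stop("duplicated cell ids")
  dt <- data.table::data.table(cell_id = as.character(cell_id),
                               condition = rep_len(as.character(condition), n),
                               experiment = rep_len(as.character(experiment), n))
  cbind(dt, data.table::as.data.table(mat))
}

#' Extract the numeric quantifier matrix from a population table
#' @param pop a table from [build_population()] (or read back via
#'   [read_table()]).
#' @return Numeric matrix, cells x 31.
#' @export
population_matrix <- function(pop) {
  qn <- summary_quantifier_names()
  missing <- setdiff(qn, names(pop))
  if (length(missing))
    stop("missing quantifier columns: ", paste(missing, collapse = ", "))
  as.matrix(as.data.frame(pop)[, qn])
}
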