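# Columnar interchange for spike rasters, hypnograms and metric tables.
# Rasters travel as a CSV event list (electrode_id, spike_time_s) plus a JSON
# sidecar carrying array metadata; times are seconds from recording start and
# electrode ids 0-based throughout.

raster_sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a spike raster to CSV + JSON sidecar
#'
#' @param raster a [spike_raster()].
#' @param path CSV path; metadata goes to the same path with a `.json`
#'   extension.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  utils::write.csv(raster$events[, c("electrode_id", "spike_time_s")], path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    n_electrodes = raster$n_electrodes, duration_s = raster$duration_s,
    array_shape = raster$array_shape, chip_id = raster$chip_id,
    group_label = raster$group_label, div = raster$div
  )
  jsonlite::write_json(meta, raster_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spike raster from CSV + JSON sidecar
#'
#' Validates every event against the recorded duration; an event at or past
#' `duration_s` is reported with its row number.
#'
#' @param path CSV path written by [write_raster()].
#' @return A [spike_raster()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  side <- raster_sidecar_path(path)
  if (!file.exists(side)) stop("missing raster metadata sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  ev <- utils::read.csv(path)
  if (!all(c("electrode_id", "spike_time_s") %in% names(ev)))
    stop("raster CSV needs header electrode_id,spike_time_s")
  spike_raster(
    events = ev, n_electrodes = meta$n_electrodes,
    duration_s = meta$duration_s, array_shape = meta$array_shape,
    chip_id = meta$chip_id %||% "chip",
    group_label = meta$group_label %||% "WT",
    div = meta$div %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Write a hypnogram to CSV
#'
#' One row per epoch: `start_s`, `state`.
#'
#' @param hyp a [hypnogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(
    start_s = (seq_along(hyp$labels) - 1) * hyp$epoch_len_s,
    state = hyp$labels
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' @param path CSV written by [write_hypnogram_csv()].
#' @param epoch_len_s epoch length; inferred from consecutive `start_s` values
#'   when NULL (a single-epoch file needs it given explicitly).
#' @return A [hypnogram()].
#' @export
read_hypnogram_csv <- function(path, epoch_len_s = NULL) {
  df <- utils::read.csv(path)
  if (is.null(epoch_len_s)) {
    if (nrow(df) < 2)
      stop("cannot infer epoch_len_s from a single epoch; pass it explicitly")
    epoch_len_s <- df$start_s[2] - df$start_s[1]
  }
  hypnogram(df$state, epoch_len_s)
}

#' Write a long-format metrics table to CSV
#'
#' @param table data.frame of metrics (any columns; typically subject/chip id,
#'   group label, metric, value).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
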