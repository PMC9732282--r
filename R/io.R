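#' Write / read a roving event table
#'
#' Tab-delimited UTF-8 text, one row per event, header columns `index`,
#' `run`, `pitch`, `role`, `train_id`, `onset_s`.
#'
#' @param seq a `stimulus_sequence`.
#' @param path file path.
#' @return `write_events` invisibly returns `path`; `read_events` returns a
#'   validated `stimulus_sequence`.
#' @export
write_events <- function(seq, path) {
  utils::write.table(as.data.frame(seq)[, c("index", "run", "pitch", "role",
                                            "train_id", "onset_s")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  ev <- structure(ev, class = c("stimulus_sequence", "data.frame"))
  validate_sequence(ev)
  ev
}

#' Write / read a surprise series next to its event table
#'
#' Two tab-delimited columns (`index`, `surprise`) plus a JSON sidecar
#' (`<path>.json`) recording the observer configuration.
#'
#' @param surprise a [surprise_series()].
#' @param seq the matching `stimulus_sequence`.
#' @param path file path for the TSV.
#' @param config the [observer_config()] used (stored in the sidecar).
#' @return `write_surprise` invisibly returns `path`; `read_surprise`
#'   returns a `surprise_series`.
#' @export
write_surprise <- function(surprise, seq, path,
                           config = observer_config()) {
  utils::write.table(data.frame(index = seq$index,
                                surprise = as.numeric(surprise)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(units = attr(surprise, "units") %||% config$units,
                  prior_counts = as.list(config$prior_counts),
                  forgetting = config$forgetting,
                  reverse_kl = config$reverse_kl,
                  config_hash = config_fingerprint(config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_surprise
#' @export
read_surprise <- function(path) {
  tab <- utils::read.delim(path)
  units <- "nats"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    units <- jsonlite::read_json(sidecar)$units %||% "nats"
  structure(tab$surprise, units = units, class = "surprise_series")
}

#' Write an ERP wave as a delimited wide table
#'
#' Tab-delimited: a `time_s` column followed by one column per channel;
#' JSON sidecar (`<path>.json`) records the selector label and trial count.
#'
#' @param wave an [erp_wave()].
#' @param path file path for the TSV.
#' @return invisibly, `path`.
#' @export
write_erp <- function(wave, path) {
  tab <- data.frame(time_s = wave$times, t(wave$data), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(label = wave$label, n_trials = wave$n_trials,
                            channels = wave$channels),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read an epoch array to a raw binary container
#'
#' One directory per subject/condition: `data.bin` holds the channels x
#' time x trials array as little-endian 32-bit floats in column-major
#' (channel-fastest) order; `meta.json` holds the shape, channel labels and
#' positions, time axis and per-trial metadata.
#'
#' @param epochs an [epoch_array()].
#' @param dir directory to create/fill.
#' @return `write_epochs` invisibly returns `dir`; `read_epochs` returns an
#'   [epoch_array()].
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 4, endian = "little")
  meta <- list(shape = dim(epochs$data),
               channels = epochs$channels,
               positions = epochs$positions,
               times = epochs$times,
               sampling_rate = epochs$sampling_rate,
               trials = epochs$trials)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(shape), size = 4,
               endian = "little")
  epoch_array(array(x, shape), meta$channels, meta$times,
              as.data.frame(meta$trials),
              positions = if (!is.null(meta$positions))
                as.data.frame(meta$positions),
              sampling_rate = meta$sampling_rate)
}

#' Write / read a behaviour score table
#'
#' Tab-delimited columns `subject`, `condition`, `block`, `score`.
#'
#' @param table a `behavior_table`.
#' @param path file path.
#' @return `write_behavior` invisibly returns `path`; `read_behavior`
#'   returns a `behavior_table`.
#' @export
write_behavior <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "block", "score")
  if (!all(need %in% names(tab)))
    stop_input("behaviour table lacks column(s): ",
               paste(setdiff(need, names(tab)), collapse = ", "))
  class(tab) <- c("behavior_table", "data.frame")
  tab
}
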