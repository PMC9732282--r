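#' ERP wave container
#'
#' @param data channels x time matrix of average amplitudes (microvolts).
#' @param times time axis in seconds.
#' @param channels channel labels.
#' @param n_trials number of trials averaged (>= 1).
#' @param label condition/selector label.
#' @return an `erp_wave` list.
#' @export
erp_wave <- function(data, times, channels, n_trials, label = "") {
  if (nrow(data) != length(channels) || ncol(data) != length(times))
    stop_input("erp_wave axes inconsistent")
  if (n_trials < 1) stop_input("n_trials must be >= 1")
  rownames(data) <- channels
  structure(list(data = data, times = times, channels = channels,
                 n_trials = n_trials, label = label),
            class = "erp_wave")
}

#' @export
print.erp_wave <- function(x, ...) {
  cat("ERP wave '", x$label, "': ", length(x$channels), " channels x ",
      length(x$times), " samples, ", x$n_trials, " trials\n", sep = "")
  invisible(x)
}

# resolve a trial selector (logical / integer / predicate on metadata)
.select_trials <- function(epochs, selector, label) {
  n <- nrow(epochs$trials)
  idx <- if (is.function(selector)) which(selector(epochs$trials))
  else if (is.logical(selector)) which(selector)
  else as.integer(selector)
  if (length(idx) == 0L)
    stop_input("selector '", label, "' matched no trials")
  if (any(idx < 1L | idx > n))
    stop_input("selector '", label, "' indexes trials out of range")
  idx
}

#' Average epochs over a trial selection
#'
#' Pointwise arithmetic mean of the selected trials, optionally followed by
#' baseline correction (subtracting each channel's pre-onset mean).
#'
#' @param epochs an [epoch_array()].
#' @param selector trials to average: a logical vector, integer indices, or
#'   a predicate function taking the trial-metadata data.frame (e.g.
#'   `function(tr) tr$role == "deviant"`).
#' @param baseline subtract the per-channel mean over times < 0 (default
#'   FALSE).
#' @param label label stored on the result; defaults to the deparsed
#'   selector.
#' @return an [erp_wave()].
#' @export
condition_average <- function(epochs, selector, baseline = FALSE,
                              label = NULL) {
  label <- label %||% paste(deparse(substitute(selector)), collapse = " ")
  idx <- .select_trials(epochs, selector, label)
  m <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  if (baseline) m <- baseline_correct(m, epochs$times)
  erp_wave(m, epochs$times, epochs$channels, length(idx), label)
}

#' Subtract the pre-onset baseline per channel
#'
#' @param x channels x time matrix or [erp_wave()].
#' @param times time axis (ignored for `erp_wave` input).
#' @return same type as `x` with each channel's mean over times < 0
#'   subtracted.
#' @export
baseline_correct <- function(x, times = NULL) {
  if (inherits(x, "erp_wave")) {
    x$data <- baseline_correct(x$data, x$times)
    return(x)
  }
  pre <- times < 0
  if (!any(pre)) stop_input("no pre-onset samples to use as baseline")
  x - rowMeans(x[, pre, drop = FALSE])
}

#' MMN differential wave: deviant minus last-standard average
#'
#' Averages all deviant trials that are preceded by a train within the same
#' run, averages the matching last-standard trials (the event immediately
#' before each such deviant, selected by [last_standard_indices()]), and
#' subtracts standard from deviant.  Other standards never enter the
#' computation.
#'
#' @param epochs an [epoch_array()] whose trials align one-to-one with
#'   `seq`.
#' @param seq the `stimulus_sequence` the epochs were recorded under.
#' @param baseline baseline-correct the two averages before subtraction
#'   (default FALSE; the subtraction is linear, so correcting before or
#'   after the difference is equivalent).
#' @return an [erp_wave()] labelled `"mmn"`; `n_trials` is the number of
#'   deviant/last-standard pairs.
#' @export
mmn_differential <- function(epochs, seq, baseline = FALSE) {
  if (nrow(epochs$trials) != nrow(seq))
    stop_input("epochs (", nrow(epochs$trials),
               " trials) not aligned with sequence (", nrow(seq), " events)")
  std <- last_standard_indices(seq)
  dev <- attr(std, "deviant_indices")
  if (length(dev) == 0L)
    stop_input("sequence has no deviant with a preceding train; ",
               "cannot form an MMN differential")
  wd <- condition_average(epochs, dev, baseline = baseline,
                          label = "deviant")
  ws <- condition_average(epochs, as.integer(std), baseline = baseline,
                          label = "last standard")
  erp_wave(wd$data - ws$data, epochs$times, epochs$channels,
           length(dev), "mmn")
}

#' Grand average of per-subject ERP waves
#'
#' Unweighted pointwise mean of a list of [erp_wave()]s with identical
#' axes.
#'
#' @param waves list of [erp_wave()]s.
#' @return an [erp_wave()]; `n_trials` is the number of subjects averaged.
#' @export
grand_average <- function(waves) {
  if (!length(waves)) stop_input("no waves to average")
  dims <- dim(waves[[1L]]$data)
  if (!all(vapply(waves, function(w) identical(dim(w$data), dims),
                  logical(1))))
    stop_input("waves have mismatching shapes")
  m <- Reduce(`+`, lapply(waves, `[[`, "data")) / length(waves)
  erp_wave(m, waves[[1L]]$times, waves[[1L]]$channels, length(waves),
           "grand average")
}

#' Most negative deflection within a latency window
#'
#' Returns the latency and amplitude of the minimum of a channel's waveform
#' inside the window; ties are broken towards the earliest sample.  A flat
#' (constant) window is flagged as degenerate rather than silently
#' returning its first sample.
#'
#' @param wave an [erp_wave()].
#' @param channel channel label.
#' @param window_ms search window in ms, default c(100, 300).
#' @return list with `latency_ms`, `amplitude_uv`, `degenerate`.
#' @export
negative_peak <- function(wave, channel, window_ms = c(100, 300)) {
  if (!channel %in% wave$channels)
    stop_input("channel '", channel, "' not in the montage")
  t_ms <- wave$times * 1000
  in_win <- t_ms >= window_ms[1] & t_ms <= window_ms[2]
  if (!any(in_win)) stop_input("window outside the epoch")
  y <- wave$data[match(channel, wave$channels), in_win]
  i <- which.min(y)
  degenerate <- max(y) == min(y)
  if (degenerate)
    warning("flat waveform in the search window; peak is degenerate",
            call. = FALSE)
  list(latency_ms = t_ms[in_win][i], amplitude_uv = unname(y[i]),
       degenerate = degenerate)
}

#' Most positive deflection within a latency window
#'
#' Counterpart of [negative_peak()]: the maximum within the window, ties to
#' the earliest sample.
#'
#' @inheritParams negative_peak
#' @return list with `latency_ms`, `amplitude_uv`, `degenerate`.
#' @export
positive_peak <- function(wave, channel, window_ms = c(100, 300)) {
  flipped <- wave
  flipped$data <- -wave$data
  out <- negative_peak(flipped, channel, window_ms)
  out$amplitude_uv <- -out$amplitude_uv
  out
}
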