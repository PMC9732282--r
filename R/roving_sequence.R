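#' Roving-sequence configuration
#'
#' Structural parameters of a roving-oddball stimulus sequence: trains of
#' identical high- or low-pitch tones alternate pitch; the first tone of
#' each train is the Deviant, every later tone a Standard.  Defaults follow
#' the classic design: 1152 events per run, two runs, a 20% deviant rate
#' (hence mean train length 5) and a constant 1 s inter-stimulus interval.
#'
#' @param n_events_per_run events per run (default 1152).
#' @param n_runs number of runs (default 2).
#' @param deviant_fraction target proportion of deviant events in (0, 1)
#'   (default 0.20); the realised deviant count per run is
#'   `round(deviant_fraction * n_events_per_run)` unless `n_trains` is given.
#' @param isi inter-stimulus onset interval in seconds (default 1).
#' @param train_length_support allowed train lengths, integers >= 2
#'   (default 3:7, mean 5 so that the 80/20 ratio holds).
#' @param n_trains optional explicit number of trains per run, overriding
#'   the deviant-fraction rule (e.g. to reproduce designs quoting a fixed
#'   number of deviant/last-standard pairs).
#' @param balance_tol maximum tolerated absolute gap between the per-pitch
#'   mean Bayesian surprise values, in nats (default 0.05).
#' @param max_retries retries of the train-order permutation used to meet
#'   `balance_tol` (default 200).
#' @param seed integer seed for reproducible generation, or NULL.
#' @return a `sequence_config` list.
#' @export
sequence_config <- function(n_events_per_run = 1152, n_runs = 2,
                            deviant_fraction = 0.20, isi = 1.0,
                            train_length_support = 3:7, n_trains = NULL,
                            balance_tol = 0.05, max_retries = 200,
                            seed = NULL) {
  if (!(deviant_fraction > 0 && deviant_fraction < 1))
    stop_input("deviant_fraction must be in (0, 1)")
  train_length_support <- sort(unique(as.integer(train_length_support)))
  if (any(train_length_support < 2))
    stop_input("train lengths must all be >= 2")
  if (n_events_per_run < min(train_length_support))
    stop_input("n_events_per_run smaller than the shortest allowed train")
  structure(list(n_events_per_run = as.integer(n_events_per_run),
                 n_runs = as.integer(n_runs),
                 deviant_fraction = deviant_fraction,
                 isi = isi,
                 train_length_support = train_length_support,
                 n_trains = if (!is.null(n_trains)) as.integer(n_trains),
                 balance_tol = balance_tol,
                 max_retries = as.integer(max_retries),
                 seed = seed),
            class = "sequence_config")
}

# draw train lengths from the support and nudge them by single-notch moves
# within the support until they sum exactly to n_events
.draw_train_lengths <- function(n_events, n_trains, support) {
  lengths <- sample(support, n_trains, replace = TRUE)
  repeat {
    delta <- n_events - sum(lengths)
    if (delta == 0L) return(lengths)
    if (delta > 0L) {
      movable <- which(lengths < max(support))
      i <- movable[sample.int(length(movable), 1L)]
      lengths[i] <- min(support[support > lengths[i]])
    } else {
      movable <- which(lengths > min(support))
      i <- movable[sample.int(length(movable), 1L)]
      lengths[i] <- max(support[support < lengths[i]])
    }
  }
}

# swap lengths between odd and even train positions until the per-pitch
# event counts are as close as the parity of the total allows
.balance_pitch_counts <- function(lengths) {
  n <- length(lengths)
  odd <- seq(1L, n, by = 2L)
  even <- if (n >= 2L) seq(2L, n, by = 2L) else integer(0)
  gap <- function(l) sum(l[odd]) - sum(l[even])
  for (iter in seq_len(4L * n)) {
    d <- gap(lengths)
    if (abs(d) <= 1L) break
    # a swap of positions (i in odd, j in even) changes d by 2*(l[j]-l[i])
    want <- -d / 2
    best <- NULL; best_gain <- 0
    for (i in odd) for (j in even) {
      change <- 2L * (lengths[j] - lengths[i])
      gain <- abs(d) - abs(d + change)
      if (gain > best_gain) { best <- c(i, j); best_gain <- gain }
    }
    if (is.null(best)) break
    tmp <- lengths[best[1L]]
    lengths[best[1L]] <- lengths[best[2L]]
    lengths[best[2L]] <- tmp
  }
  lengths
}

.run_from_lengths <- function(lengths, start_pitch, isi, run_id,
                              first_index, first_train) {
  n <- sum(lengths)
  pitch_of_train <- rep(c(start_pitch, setdiff(c("high", "low"), start_pitch)),
                        length.out = length(lengths))
  pitch <- rep(pitch_of_train, times = lengths)
  train_local <- rep(seq_along(lengths), times = lengths)
  role <- ifelse(c(TRUE, diff(train_local) != 0L), "deviant", "standard")
  data.frame(index = seq.int(first_index, length.out = n),
             run = run_id,
             pitch = pitch,
             role = role,
             train_id = first_train + train_local - 1L,
             onset_s = (seq_len(n) - 1L) * isi,
             stringsAsFactors = FALSE)
}

#' Generate a roving-oddball stimulus sequence
#'
#' Draws pseudo-random train lengths from the configured support, adjusts
#' them so each run has exactly `n_events_per_run` events and the target
#' number of trains (= deviants), balances the number of events per pitch,
#' and then permutes the train-length order (within pitch positions, up to
#' `max_retries` times) until the per-pitch mean Bayesian surprise under the
#' default ideal observer differs by at most `balance_tol` nats.  Within a
#' run consecutive trains alternate pitch, the first event of every train is
#' the Deviant, and onsets advance by `isi` seconds.
#'
#' @param config a [sequence_config()].
#' @return a `stimulus_sequence`: data.frame with columns `index`, `run`,
#'   `pitch`, `role`, `train_id`, `onset_s` and the config as attribute.
#' @export
#' @examples
#' seq <- generate_sequence(sequence_config(n_events_per_run = 60,
#'                                          n_runs = 1, seed = 1))
#' table(seq$role)
generate_sequence <- function(config = sequence_config()) {
  stopifnot(inherits(config, "sequence_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  support <- config$train_length_support
  n <- config$n_events_per_run
  n_trains <- config$n_trains %||%
    max(1L, as.integer(round(config$deviant_fraction * n)))
  if (n < n_trains * min(support) || n > n_trains * max(support))
    stop_input("infeasible configuration: no combination of ", n_trains,
               " train lengths from {", paste(support, collapse = ","),
               "} sums to ", n, " events")
  runs <- vector("list", config$n_runs)
  first_index <- 1L; first_train <- 1L
  for (r in seq_len(config$n_runs)) {
    lengths <- .draw_train_lengths(n, n_trains, support)
    lengths <- .balance_pitch_counts(lengths)
    start_pitch <- sample(c("high", "low"), 1L)
    best_run <- NULL; best_gap <- Inf
    odd <- seq(1L, n_trains, by = 2L)
    even <- if (n_trains >= 2L) seq(2L, n_trains, by = 2L) else integer(0)
    for (try in seq_len(max(1L, config$max_retries))) {
      run <- .run_from_lengths(lengths, start_pitch, config$isi, r,
                               first_index, first_train)
      s <- surprise_series(run, observer_config())
      # a single-train run has one pitch only: nothing to balance
      gap <- if (length(unique(run$pitch)) < 2) 0
      else abs(mean(s[run$pitch == "high"]) - mean(s[run$pitch == "low"]))
      if (gap < best_gap) { best_gap <- gap; best_run <- run }
      if (gap <= config$balance_tol) break
      # permute within-pitch positions: keeps counts, changes the ordering
      lengths[odd] <- lengths[sample(odd)]
      if (length(even)) lengths[even] <- lengths[sample(even)]
    }
    runs[[r]] <- best_run
    first_index <- first_index + n
    first_train <- first_train + n_trains
  }
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  structure(out, config = config,
            class = c("stimulus_sequence", "data.frame"))
}

#' Validate the structure of a stimulus sequence
#'
#' Re-derives event roles from pitch changes (deviant iff the pitch differs
#' from the previous event or the event starts a run) and checks train-id
#' bookkeeping, pitch alternation across trains, and the constant-ISI onset
#' grid.  Errors describe the first violated property.
#'
#' @param seq a `stimulus_sequence` (or any data.frame with its columns).
#' @return invisibly TRUE when the sequence is valid.
#' @export
validate_sequence <- function(seq) {
  need <- c("index", "run", "pitch", "role", "train_id", "onset_s")
  if (!all(need %in% names(seq)))
    stop_input("sequence lacks column(s): ",
               paste(setdiff(need, names(seq)), collapse = ", "))
  if (is.unsorted(seq$index, strictly = TRUE))
    stop_input("events out of order: index must be strictly increasing")
  for (r in unique(seq$run)) {
    ev <- seq[seq$run == r, , drop = FALSE]
    run_start <- c(TRUE, rep(FALSE, nrow(ev) - 1L))
    derived <- ifelse(run_start | c(TRUE, ev$pitch[-1L] !=
                                      ev$pitch[-nrow(ev)]),
                      "deviant", "standard")
    derived[1L] <- "deviant"
    if (!identical(derived, ev$role))
      stop_input("run ", r, ": roles inconsistent with pitch changes")
    new_train <- ev$role == "deviant"
    if (!identical(cumsum(new_train) - 1L + ev$train_id[1L], ev$train_id))
      stop_input("run ", r, ": train_id inconsistent with deviant events")
    tp <- ev$pitch[new_train]
    if (length(tp) > 1L && any(tp[-1L] == tp[-length(tp)]))
      stop_input("run ", r, ": consecutive trains do not alternate pitch")
    isi <- attr(seq, "config")$isi %||% diff(ev$onset_s)[1L]
    if (nrow(ev) > 1L &&
        max(abs(diff(ev$onset_s) - isi)) > 1e-9)
      stop_input("run ", r, ": onsets not on a constant-ISI grid")
  }
  invisible(TRUE)
}

#' Indices of the last standard before each deviant
#'
#' For every deviant that is preceded by a train within the same run,
#' returns the index (row number) of the immediately preceding event - the
#' last standard of the prior train.  The first train of each run
#' contributes no entry, so a run with k trains yields k - 1 indices.
#'
#' @param seq a `stimulus_sequence`.
#' @return integer vector of row indices into `seq`, with the row indices of
#'   the paired deviants as attribute `deviant_indices`.
#' @export
#' @examples
#' seq <- generate_sequence(sequence_config(n_events_per_run = 60,
#'                                          n_runs = 1, seed = 1))
#' length(last_standard_indices(seq))  # trains - 1
last_standard_indices <- function(seq) {
  if (is.unsorted(seq$index, strictly = TRUE))
    stop_input("events out of order: index must be strictly increasing")
  pos <- seq_len(nrow(seq))
  run_start <- c(TRUE, seq$run[-1L] != seq$run[-nrow(seq)])
  dev <- which(seq$role == "deviant" & !run_start)
  structure(dev - 1L, deviant_indices = dev)
}

#' Per-pitch balance report for a sequence
#'
#' Counts events and deviants per pitch and compares the mean Bayesian
#' surprise of high- against low-pitch events, summarising how well the
#' design balances stimulus exposure and informational value across pitches.
#'
#' @param seq a `stimulus_sequence`.
#' @param surprise a [surprise_series()] aligned with `seq` (one value per
#'   event).
#' @return a `balance_report` list: `n_events_per_pitch`,
#'   `n_deviants_per_pitch`, `mean_surprise_per_pitch`,
#'   `max_abs_surprise_gap` (same units as `surprise`).
#' @export
balance_report <- function(seq, surprise) {
  if (length(surprise) != nrow(seq))
    stop_input("surprise length (", length(surprise),
               ") does not match number of events (", nrow(seq), ")")
  pitches <- c("high", "low")
  n_ev <- vapply(pitches, function(p) sum(seq$pitch == p), integer(1))
  n_dev <- vapply(pitches, function(p)
    sum(seq$pitch == p & seq$role == "deviant"), integer(1))
  ms <- vapply(pitches, function(p)
    mean(as.numeric(surprise)[seq$pitch == p]), numeric(1))
  structure(list(n_events_per_pitch = n_ev,
                 n_deviants_per_pitch = n_dev,
                 mean_surprise_per_pitch = ms,
                 max_abs_surprise_gap = abs(diff(ms))[[1L]],
                 units = attr(surprise, "units") %||% "nats"),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Roving-sequence balance report\n")
  cat("  events per pitch:  high", x$n_events_per_pitch[["high"]],
      " low", x$n_events_per_pitch[["low"]], "\n")
  cat("  deviants per pitch: high", x$n_deviants_per_pitch[["high"]],
      " low", x$n_deviants_per_pitch[["low"]], "\n")
  cat(sprintf("  mean surprise (%s): high %.5f  low %.5f  gap %.5f\n",
              x$units, x$mean_surprise_per_pitch[["high"]],
              x$mean_surprise_per_pitch[["low"]], x$max_abs_surprise_gap))
  invisible(x)
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Roving stimulus sequence: ", nrow(x), " events, ",
      length(unique(x$run)), " run(s), ",
      sum(x$role == "deviant"), " deviants\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
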