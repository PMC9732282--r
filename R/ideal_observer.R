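#' Ideal-observer configuration
#'
#' A sequential Bayesian learner of stimulus probabilities: a conjugate
#' Beta-Bernoulli model over the two pitch categories.  Before each update
#' the accumulated counts may be decayed towards the prior by a forgetting
#' factor `lambda`; the observed category's count is then incremented.  The
#' per-trial Bayesian surprise is the KL divergence between the updated and
#' the pre-update belief.
#'
#' @param prior_counts positive pseudo-counts per category, named
#'   `high`/`low` (default c(1, 1), a uniform prior).
#' @param forgetting decay factor lambda in (0, 1] applied to the
#'   accumulated counts (as excess over the prior) before each update;
#'   1 (default) means no forgetting, i.e. plain conjugate updating.
#' @param units `"nats"` (default) or `"bits"` for reported surprise.
#' @param reverse_kl if TRUE report KL(pre-update || updated) instead of the
#'   standard Bayesian-surprise direction KL(updated || pre-update).
#' @return an `observer_config` list.
#' @export
observer_config <- function(prior_counts = c(high = 1, low = 1),
                            forgetting = 1,
                            units = c("nats", "bits"),
                            reverse_kl = FALSE) {
  units <- match.arg(units)
  if (is.null(names(prior_counts)))
    names(prior_counts) <- c("high", "low")
  if (any(prior_counts <= 0)) stop_input("prior_counts must be > 0")
  if (!(forgetting > 0 && forgetting <= 1))
    stop_input("forgetting must be in (0, 1]")
  structure(list(prior_counts = prior_counts, forgetting = forgetting,
                 units = units, reverse_kl = reverse_kl),
            class = "observer_config")
}

#' Fresh observer state
#'
#' @param config an [observer_config()].
#' @return an `observer_state` list with `counts` (initialised at the prior)
#'   and `n_observed = 0`.
#' @export
observer_state <- function(config = observer_config()) {
  structure(list(counts = config$prior_counts, n_observed = 0L),
            class = "observer_state")
}

#' KL divergence between two Beta distributions
#'
#' Closed form for KL(Beta(post_a, post_b) || Beta(prior_a, prior_b)) in
#' nats, via log-Beta and digamma terms.  Always non-negative.
#'
#' @param post_a,post_b parameters of the first (posterior) Beta; > 0.
#' @param prior_a,prior_b parameters of the second (prior) Beta; > 0.
#' @return KL divergence in nats.
#' @export
#' @examples
#' beta_kl(2, 1, 1, 1)  # ~0.1931 nats
beta_kl <- function(post_a, post_b, prior_a, prior_b) {
  if (any(c(post_a, post_b, prior_a, prior_b) <= 0))
    stop_input("Beta parameters must all be > 0")
  lbeta(prior_a, prior_b) - lbeta(post_a, post_b) +
    (post_a - prior_a) * digamma(post_a) +
    (post_b - prior_b) * digamma(post_b) +
    (prior_a + prior_b - post_a - post_b) * digamma(post_a + post_b)
}

#' Observe one stimulus and return the updated state and its surprise
#'
#' The state's counts are decayed towards the prior by the forgetting
#' factor, the observed category's count is incremented, and the Bayesian
#' surprise of the update - KL between the incremented and the decayed
#' (pre-increment) Beta belief - is returned in the configured units.
#'
#' @param state an [observer_state()].
#' @param category observed category, `"high"` or `"low"`.
#' @param config an [observer_config()].
#' @return list with elements `state` (updated) and `surprise`.
#' @export
observe <- function(state, category, config = observer_config()) {
  counts <- state$counts
  if (!category %in% names(counts))
    stop_input("unknown category '", category, "'; expected one of: ",
               paste(names(counts), collapse = ", "))
  lam <- config$forgetting
  pre <- config$prior_counts + lam * (counts - config$prior_counts)
  post <- pre
  post[category] <- post[category] + 1
  s <- if (config$reverse_kl)
    beta_kl(pre[1L], pre[2L], post[1L], post[2L])
  else
    beta_kl(post[1L], post[2L], pre[1L], pre[2L])
  if (config$units == "bits") s <- s / log(2)
  list(state = structure(list(counts = post,
                              n_observed = state$n_observed + 1L),
                         class = "observer_state"),
       surprise = unname(s))
}

#' Per-trial Bayesian surprise for a stimulus sequence
#'
#' Applies the sequential observer to the pitch stream, restarting from the
#' prior at the beginning of each run (no cross-run carry-over), and returns
#' one surprise value per event.
#'
#' @param seq a `stimulus_sequence` (any data.frame with `pitch` and `run`
#'   columns; a bare character vector of pitches is treated as one run).
#' @param config an [observer_config()].
#' @return a `surprise_series`: numeric vector, one non-negative value per
#'   event, with attribute `units`.
#' @export
#' @examples
#' seq <- generate_sequence(sequence_config(n_events_per_run = 60,
#'                                          n_runs = 1, seed = 1))
#' s <- surprise_series(seq)
#' length(s); all(s >= 0)
surprise_series <- function(seq, config = observer_config()) {
  if (is.character(seq))
    seq <- data.frame(pitch = seq, run = 1L, stringsAsFactors = FALSE)
  n <- nrow(seq)
  out <- numeric(n)
  if (n > 0L) {
    for (r in unique(seq$run)) {
      idx <- which(seq$run == r)
      if (config$forgetting == 1) {
        # conjugate counts are cumulative sums; beta_kl vectorises
        is_high <- seq$pitch[idx] == names(config$prior_counts)[1L]
        a_post <- config$prior_counts[[1L]] + cumsum(is_high)
        b_post <- config$prior_counts[[2L]] + cumsum(!is_high)
        a_pre <- a_post - is_high
        b_pre <- b_post - !is_high
        s <- if (config$reverse_kl)
          beta_kl(a_pre, b_pre, a_post, b_post)
        else
          beta_kl(a_post, b_post, a_pre, b_pre)
        out[idx] <- if (config$units == "bits") s / log(2) else s
      } else {
        st <- observer_state(config)
        for (i in idx) {
          res <- observe(st, seq$pitch[i], config)
          st <- res$state
          out[i] <- res$surprise
        }
      }
    }
  }
  structure(out, units = config$units, class = "surprise_series")
}

#' @export
print.surprise_series <- function(x, ...) {
  cat("Bayesian surprise series: ", length(x), " trials (",
      attr(x, "units"), "), mean ", signif(mean(x), 4), "\n", sep = "")
  invisible(x)
}

#' Sensitivity sweep of mean surprise over forgetting factors
#'
#' Recomputes the surprise series for a grid of forgetting factors, to show
#' how the (unreported, assumption-laden) forgetting constant changes the
#' scale and the deviant/standard contrast of the surprise regressor.
#'
#' @param seq a `stimulus_sequence`.
#' @param lambdas grid of forgetting factors in (0, 1].
#' @param config base [observer_config()]; its `forgetting` is overridden.
#' @return data.frame with one row per lambda: mean surprise overall, over
#'   deviants and over standards.
#' @export
forgetting_sweep <- function(seq, lambdas = seq(0.9, 1, by = 0.02),
                             config = observer_config()) {
  rows <- lapply(lambdas, function(l) {
    cfg <- config
    cfg$forgetting <- l
    s <- surprise_series(seq, cfg)
    data.frame(forgetting = l,
               mean_surprise = mean(s),
               mean_deviant = mean(s[seq$role == "deviant"]),
               mean_standard = mean(s[seq$role == "standard"]))
  })
  do.call(rbind, rows)
}
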