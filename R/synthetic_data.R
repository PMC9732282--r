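#' ERP component template
#'
#' A scalp component with a Gaussian time course (peak latency, width as
#' Gaussian SD) and a per-channel topography in `[-1, 1]`.
#'
#' @param name component label.
#' @param peak_ms peak latency in ms post-onset.
#' @param width_ms Gaussian SD of the time course in ms; > 0.
#' @param amplitude signed peak amplitude in microvolts.
#' @param topography named numeric vector of per-channel weights.
#' @return an `erp_template` list.
#' @export
erp_template <- function(name, peak_ms, width_ms, amplitude, topography) {
  if (width_ms <= 0) stop_input("width_ms must be > 0")
  structure(list(name = name, peak_ms = peak_ms, width_ms = width_ms,
                 amplitude = amplitude, topography = topography),
            class = "erp_template")
}

#' Gaussian scalp topography over montage positions
#'
#' @param montage data.frame with `channel`, `x`, `y`.
#' @param center 2-D coordinates of the topography peak.
#' @param sigma spatial Gaussian SD in montage units.
#' @return named weight vector, 1 at the centre falling off with distance.
#' @export
scalp_topography <- function(montage, center, sigma = 0.6) {
  d2 <- (montage$x - center[1])^2 + (montage$y - center[2])^2
  w <- exp(-d2 / (2 * sigma^2))
  names(w) <- montage$channel
  w
}

#' Default auditory ERP component templates
#'
#' N1, P2, P3 and N4 are deterministic background components present on
#' every trial; the MMN template (unit negative amplitude, frontocentral
#' topography peaking exactly at Fz, 210 ms latency) is scaled per trial by
#' the condition gain times the trial's Bayesian surprise.
#'
#' @param montage montage data.frame (default [default_montage()]).
#' @return named list of [erp_template()] objects.
#' @export
default_erp_templates <- function(montage = default_montage()) {
  fz <- montage[montage$channel == "Fz", c("x", "y")]
  mmn_center <- if (nrow(fz)) as.numeric(fz) else c(0, 0.45)
  list(
    N1 = erp_template("N1", 100, 20, -2.0,
                      scalp_topography(montage, c(0, 0.30), 0.70)),
    P2 = erp_template("P2", 185, 25, 1.5,
                      scalp_topography(montage, c(0, 0.20), 0.70)),
    MMN = erp_template("MMN", 210, 18, -1.0,
                       scalp_topography(montage, mmn_center, 0.55)),
    P3 = erp_template("P3", 320, 45, 2.5,
                      scalp_topography(montage, c(0, -0.45), 0.70)),
    N4 = erp_template("N4", 450, 50, -1.5,
                      scalp_topography(montage, c(0, -0.10), 0.70))
  )
}

#' Simulation configuration for the synthetic study
#'
#' Defaults describe the emulated study: 18 subjects, three presence
#' conditions where physical co-presence doubles the MMN gain relative to
#' being alone or connected by video-call, a 32-channel 10-20 montage,
#' 250 Hz sampling over a -0.15 s to +0.85 s epoch, and additive white
#' noise.  The gains are expressed in microvolts per nat of Bayesian
#' surprise; the defaults (solo 300, other 600, virtual 300) are calibrated
#' so that mean deviant surprise of a default-length run (about 0.005 nats)
#' yields MMN differential amplitudes near -1.4 uV (solo/virtual) and
#' -2.8 uV (other).
#'
#' @param n_subjects number of subjects (default 18, >= 2).
#' @param conditions named numeric vector of per-condition MMN gains in
#'   microvolts per nat.
#' @param montage montage data.frame.
#' @param sampling_rate sampling rate in Hz (default 250).
#' @param epoch_window epoch limits in seconds, half-open `[t0, t1)`
#'   (default c(-0.15, 0.85)); the realised time axis is the sample grid
#'   anchored at 0 (so 0 is always a sample) restricted to the window.
#' @param noise_sd additive noise SD in microvolts (default 2.5).
#' @param noise_model `"white"` (default) or `"ar1"`.
#' @param ar_coef lag-1 coefficient for AR1 noise (default 0.9).
#' @param subject_sd SD of the multiplicative between-subject gain factor
#'   (default 0.2; factor = 1 + N(0, subject_sd)).
#' @param mmn_scope `"deviant"` (default): surprise-scaled MMN added on
#'   deviant trials only (differential-wave logic); `"all"`: added on every
#'   trial (so standards also carry surprise signal, as assumed by the
#'   trial-by-trial correlation analysis).
#' @param templates list of [erp_template()]s; default built from `montage`.
#' @param seed integer seed or NULL.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 18,
                              conditions = c(solo = 300, other = 600,
                                             virtual = 300),
                              montage = default_montage(),
                              sampling_rate = 250,
                              epoch_window = c(-0.15, 0.85),
                              noise_sd = 2.5,
                              noise_model = c("white", "ar1"),
                              ar_coef = 0.9,
                              subject_sd = 0.2,
                              mmn_scope = c("deviant", "all"),
                              templates = NULL,
                              seed = NULL) {
  noise_model <- match.arg(noise_model)
  mmn_scope <- match.arg(mmn_scope)
  if (n_subjects < 2) stop_input("n_subjects must be >= 2")
  if (!all(is.finite(conditions))) stop_input("condition gains must be finite")
  if (is.null(names(conditions)))
    stop_input("conditions must be a named gain vector")
  len <- diff(epoch_window) * sampling_rate
  if (abs(len - round(len)) > 1e-9)
    stop_input("epoch length times sampling_rate must be integral")
  if (is.null(templates)) templates <- default_erp_templates(montage)
  for (tp in templates)
    if (!all(montage$channel %in% names(tp$topography)))
      stop_input("template '", tp$name,
                 "' lacks topography weights for some montage channels")
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions, montage = montage,
                 sampling_rate = sampling_rate,
                 epoch_window = epoch_window, noise_sd = noise_sd,
                 noise_model = noise_model, ar_coef = ar_coef,
                 subject_sd = subject_sd, mmn_scope = mmn_scope,
                 templates = templates, seed = seed),
            class = "simulation_config")
}

#' Epoch time axis implied by a simulation configuration
#'
#' Samples lie on the grid `k / sampling_rate` (so t = 0 is always a
#' sample) and cover the half-open epoch window.
#'
#' @param config a [simulation_config()].
#' @return numeric vector of sample times in seconds.
#' @export
epoch_times <- function(config) {
  r <- config$sampling_rate
  k0 <- ceiling(config$epoch_window[1] * r - 1e-9)
  k1 <- ceiling(config$epoch_window[2] * r - 1e-9) - 1
  seq(k0, k1) / r
}

# unit-peak template time course on the epoch axis (times in s, peak in ms)
.template_course <- function(template, times) {
  exp(-((times * 1000 - template$peak_ms)^2) / (2 * template$width_ms^2))
}

# channels x time matrix of one template on a montage (includes amplitude)
.template_matrix <- function(template, montage, times) {
  w <- template$topography[montage$channel]
  outer(unname(w) * template$amplitude, .template_course(template, times))
}

.noise_cube <- function(config, nch, nt, ntr) {
  if (config$noise_model == "white")
    return(array(stats::rnorm(nch * nt * ntr, 0, config$noise_sd),
                 c(nch, nt, ntr)))
  rho <- config$ar_coef
  x <- array(0, c(nch, nt, ntr))
  x[, 1, ] <- stats::rnorm(nch * ntr, 0, config$noise_sd)
  innov_sd <- config$noise_sd * sqrt(1 - rho^2)
  for (j in 2:nt)
    x[, j, ] <- rho * x[, j - 1, ] +
      stats::rnorm(nch * ntr, 0, innov_sd)
  x
}

#' Epoch-array container
#'
#' @param data channels x time x trials array of amplitudes (microvolts).
#' @param channels channel labels (length = dim 1).
#' @param times time axis in seconds (length = dim 2).
#' @param trials data.frame of per-trial metadata (rows = dim 3).
#' @param positions optional montage data.frame.
#' @param sampling_rate sampling rate in Hz.
#' @return an `epoch_array` list.
#' @export
epoch_array <- function(data, channels, times, trials, positions = NULL,
                        sampling_rate = NULL) {
  d <- dim(data)
  if (length(d) != 3) stop_input("data must be channels x time x trials")
  if (d[1] != length(channels) || d[2] != length(times) ||
      d[3] != nrow(trials))
    stop_input("epoch axes inconsistent with channels/times/trials metadata")
  dimnames(data) <- list(channels, NULL, NULL)
  structure(list(data = data, channels = channels, times = times,
                 trials = trials, positions = positions,
                 sampling_rate = sampling_rate),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat("Epoch array: ", length(x$channels), " channels x ",
      length(x$times), " samples x ", nrow(x$trials), " trials  [",
      signif(min(x$times), 3), ", ", signif(max(x$times), 3), "] s\n",
      sep = "")
  invisible(x)
}

#' Simulate multichannel EEG epochs for a stimulus sequence
#'
#' Every trial is the sum of the deterministic background components (N1,
#' P2, P3, N4), a mismatch response - the MMN template scaled by the
#' condition gain, the subject's gain factor and the trial's Bayesian
#' surprise, applied on deviant trials (or on all trials when
#' `mmn_scope = "all"`) - and additive noise.  Subjects share the stimulus
#' sequence; noise and gain factors are drawn per subject and condition.
#'
#' @param seq a `stimulus_sequence`.
#' @param surprise aligned [surprise_series()] (one value per event).
#' @param config a [simulation_config()].
#' @param conditions optional character vector restricting which configured
#'   conditions are simulated.
#' @param subjects optional integer indices of the subjects to simulate
#'   (default all).  Subject gain factors and per-subject noise streams are
#'   derived deterministically from `config$seed`, so simulating subjects
#'   one at a time reproduces the corresponding subjects of a full run.
#' @return named list (subject) of named lists (condition) of
#'   [epoch_array()]s.
#' @export
simulate_epochs <- function(seq, surprise, config = simulation_config(),
                            conditions = NULL, subjects = NULL) {
  if (length(surprise) != nrow(seq))
    stop_input("surprise length (", length(surprise),
               ") does not match number of events (", nrow(seq), ")")
  conditions <- conditions %||% names(config$conditions)
  unknown <- setdiff(conditions, names(config$conditions))
  if (length(unknown))
    stop_input("unknown condition(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)
  montage <- config$montage
  times <- epoch_times(config)
  nch <- nrow(montage); nt <- length(times); ntr <- nrow(seq)
  is_mmn <- vapply(config$templates, function(tp) tp$name == "MMN",
                   logical(1))
  base <- Reduce(`+`, lapply(config$templates[!is_mmn], .template_matrix,
                             montage = montage, times = times),
                 accumulate = FALSE, right = FALSE,
                 init = matrix(0, nch, nt))
  mmn_tpl <- config$templates[is_mmn][[1L]]
  mmn_mat <- .template_matrix(mmn_tpl, montage, times)
  on_trial <- if (config$mmn_scope == "deviant")
    as.numeric(seq$role == "deviant") else rep(1, ntr)
  s <- as.numeric(surprise)
  gain_factor <- 1 + stats::rnorm(config$n_subjects, 0, config$subject_sd)
  subjects <- subjects %||% seq_len(config$n_subjects)
  if (any(subjects < 1L | subjects > config$n_subjects))
    stop_input("subjects out of range 1..", config$n_subjects)
  all_names <- sprintf("subject_%02d", seq_len(config$n_subjects))
  out <- vector("list", length(subjects))
  names(out) <- all_names[subjects]
  for (k in seq_along(subjects)) {
    si <- subjects[k]
    if (!is.null(config$seed)) set.seed(derive_seed(config$seed, 7000 + si))
    per_cond <- vector("list", length(conditions))
    names(per_cond) <- conditions
    for (cn in conditions) {
      coef <- config$conditions[[cn]] * gain_factor[si] * s * on_trial
      cube <- array(base, c(nch, nt, ntr)) +
        array(outer(as.vector(mmn_mat), coef), c(nch, nt, ntr)) +
        .noise_cube(config, nch, nt, ntr)
      meta <- data.frame(index = seq$index, run = seq$run,
                         pitch = seq$pitch, role = seq$role,
                         surprise = s, condition = cn,
                         subject = all_names[si],
                         stringsAsFactors = FALSE)
      per_cond[[cn]] <- epoch_array(cube, montage$channel, times, meta,
                                    positions = montage,
                                    sampling_rate = config$sampling_rate)
    }
    out[[k]] <- per_cond
  }
  out
}

#' Simulate behavioural memory-task scores
#'
#' Each block score is a Binomial(n_items, p) draw where the success
#' probability combines the condition mean with a shared subject random
#' effect and a subject-by-condition random effect, both on the logit
#' scale.  The shared effect models stable individual memory ability (it
#' cancels in paired contrasts); the condition-specific effect models
#' session-to-session variability, which is what limits the power of the
#' paired tests.  Defaults reproduce typical object-location recall
#' accuracies near 70% (solo), 79% (physical co-presence) and 64%
#' (video-call), scored out of 16 items over 3 blocks.
#'
#' @param config a [simulation_config()] (supplies `n_subjects` and `seed`).
#' @param condition_means named vector of condition success proportions in
#'   \[0, 1\].
#' @param n_items items per block (default 16).
#' @param n_blocks blocks per subject and condition (default 3).
#' @param subject_sd SD of the shared subject effect, logit scale
#'   (default 0.8).
#' @param condition_sd SD of the subject-by-condition effect, logit scale
#'   (default 0.6).
#' @return a `behavior_table` data.frame with columns `subject`,
#'   `condition`, `block`, `score`.
#' @export
simulate_behavior <- function(config = simulation_config(),
                              condition_means = c(solo = 0.7025,
                                                  other = 0.794,
                                                  virtual = 0.6377),
                              n_items = 16, n_blocks = 3,
                              subject_sd = 0.8, condition_sd = 0.6) {
  if (any(condition_means < 0 | condition_means > 1))
    stop_input("condition_means must be proportions in [0, 1]")
  if (is.null(names(condition_means)))
    stop_input("condition_means must be named by condition")
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- config$n_subjects
  subjects <- sprintf("subject_%02d", seq_len(ns))
  b_subject <- stats::rnorm(ns, 0, subject_sd)
  rows <- list()
  for (ci in seq_along(condition_means)) {
    cn <- names(condition_means)[ci]
    b_cond <- stats::rnorm(ns, 0, condition_sd)
    p <- stats::plogis(stats::qlogis(condition_means[[ci]]) +
                         b_subject + b_cond)
    p[condition_means[[ci]] == 0] <- 0
    p[condition_means[[ci]] == 1] <- 1
    score <- stats::rbinom(ns * n_blocks, n_items, rep(p, each = n_blocks))
    rows[[ci]] <- data.frame(subject = rep(subjects, each = n_blocks),
                             condition = cn,
                             block = rep(seq_len(n_blocks), ns),
                             score = score,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("behavior_table", "data.frame")
  out
}
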