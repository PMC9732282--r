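#' Full-study run configuration
#'
#' Bundles the per-stage configurations of the synthetic study and its
#' analysis.  The global `seed` deterministically derives every stage's
#' seed, so a run is reproducible end to end; per-stage seeds inside the
#' sub-configurations are overridden.
#'
#' @param sequence a [sequence_config()].
#' @param observer an [observer_config()].
#' @param simulation a [simulation_config()].
#' @param cluster a [cluster_config()].
#' @param behavior_means named condition proportions for the behavioural
#'   simulation.
#' @param contrasts list of length-2 condition-name vectors for the paired
#'   MMN cluster tests; default the three presence contrasts.
#' @param correlations also compute per-condition trial-by-trial
#'   correlation maps and their one-sample cluster tests (default FALSE:
#'   the MMN contrasts and behaviour already summarise the study; the
#'   correlation stage roughly doubles the run time).
#' @param seed global integer seed (default 1).
#' @return a `run_config` list.
#' @export
run_config <- function(sequence = sequence_config(),
                       observer = observer_config(),
                       simulation = simulation_config(),
                       cluster = cluster_config(),
                       behavior_means = c(solo = 0.7025, other = 0.794,
                                          virtual = 0.6377),
                       contrasts = list(c("other", "solo"),
                                        c("other", "virtual"),
                                        c("virtual", "solo")),
                       correlations = FALSE,
                       seed = 1) {
  for (pr in contrasts)
    if (!all(pr %in% names(simulation$conditions)))
      stop_input("contrast ", paste(pr, collapse = " vs "),
                 " names a condition the simulation does not define")
  structure(list(sequence = sequence, observer = observer,
                 simulation = simulation, cluster = cluster,
                 behavior_means = behavior_means, contrasts = contrasts,
                 correlations = correlations, seed = seed),
            class = "run_config")
}

.stage_msg <- function(name, t0) {
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

.run_stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  .stage_msg(name, t0)
  out
}

#' Run the full synthetic study and analysis
#'
#' Orchestrates the pipeline: sequence generation, Bayesian surprise,
#' epoch simulation (streamed subject by subject), per-subject MMN
#' differential waves, paired spatiotemporal cluster tests for each
#' condition contrast, optional trial-by-trial correlation maps with
#' one-sample cluster tests, and the behavioural simulation with paired
#' tests under FDR control.  Event, surprise and behaviour tables plus a
#' machine-readable summary JSON are written to `out_dir`; every sidecar
#' carries the configuration fingerprint and seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); NULL to skip
#'   writing files.
#' @return invisibly, a list: `summary` (what summary.json holds), `waves`
#'   (per subject per condition MMN waves), `cluster_results`,
#'   `correlation_results` (if requested), `behavior`, `behavior_table`.
#' @export
run_study <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_fingerprint(config)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seq_cfg <- config$sequence
  seq_cfg$seed <- derive_seed(config$seed, 1L)
  seq <- .run_stage("sequence", generate_sequence(seq_cfg))
  s <- .run_stage("surprise", surprise_series(seq, config$observer))
  if (!is.null(out_dir)) {
    write_events(seq, file.path(out_dir, "events.tsv"))
    write_surprise(s, seq, file.path(out_dir, "surprise.tsv"),
                   config$observer)
  }
  sim_cfg <- config$simulation
  sim_cfg$seed <- derive_seed(config$seed, 2L)
  conds <- unique(unlist(config$contrasts))
  waves <- .run_stage("simulate+erp", {
    lapply(seq_len(sim_cfg$n_subjects), function(si) {
      eps <- simulate_epochs(seq, s, sim_cfg, conditions = conds,
                             subjects = si)[[1L]]
      out <- lapply(eps, mmn_differential, seq = seq)
      if (config$correlations)
        attr(out, "r_maps") <- lapply(eps, trialwise_correlation,
                                      surprise = s)
      out
    })
  })
  adjacency <- build_adjacency(sim_cfg$montage)
  cluster_results <- .run_stage("cluster-tests", {
    res <- lapply(seq_along(config$contrasts), function(k) {
      pr <- config$contrasts[[k]]
      cluster_permutation_test(
        maps = lapply(waves, `[[`, pr[1L]),
        maps_b = lapply(waves, `[[`, pr[2L]),
        mode = "paired", adjacency = adjacency, config = config$cluster,
        seed = derive_seed(config$seed, 10L + k))
    })
    names(res) <- vapply(config$contrasts, paste, "", collapse = "_vs_")
    res
  })
  correlation_results <- NULL
  if (config$correlations) {
    correlation_results <- .run_stage("correlation-tests", {
      res <- lapply(conds, function(cn) {
        rmaps <- lapply(waves, function(w) attr(w, "r_maps")[[cn]])
        cluster_permutation_test(
          maps = rmaps, mode = "onesample", adjacency = adjacency,
          config = config$cluster,
          seed = derive_seed(config$seed, 20L + match(cn, conds)))
      })
      names(res) <- conds
      res
    })
  }
  sim_cfg_b <- sim_cfg
  sim_cfg_b$seed <- derive_seed(config$seed, 3L)
  behavior_table <- .run_stage("behavior",
    simulate_behavior(sim_cfg_b, config$behavior_means))
  behavior <- behavior_tests(behavior_table,
                             pairs = config$contrasts,
                             q = config$cluster$alpha)
  if (!is.null(out_dir))
    write_behavior(behavior_table, file.path(out_dir, "behavior.tsv"))
  peak_channel <- if ("Fz" %in% sim_cfg$montage$channel) "Fz"
                  else sim_cfg$montage$channel[1L]
  group_peaks <- lapply(conds, function(cn) {
    ga <- grand_average(lapply(waves, `[[`, cn))
    pk <- negative_peak(ga, peak_channel)
    list(condition = cn, channel = peak_channel,
         latency_ms = pk$latency_ms, amplitude_uv = pk$amplitude_uv)
  })
  summary <- list(
    config_hash = hash,
    seed = config$seed,
    sequence = list(n_events = nrow(seq),
                    n_runs = length(unique(seq$run)),
                    n_deviants = sum(seq$role == "deviant")),
    surprise = list(mean_deviant = mean(s[seq$role == "deviant"]),
                    mean_standard = mean(s[seq$role == "standard"])),
    mmn_peaks = group_peaks,
    contrasts = lapply(names(cluster_results), function(nm) {
      cl <- cluster_results[[nm]]$clusters
      sig <- cl[cl$significant, , drop = FALSE]
      list(contrast = nm,
           n_clusters = nrow(cl),
           n_significant = nrow(sig),
           significant = if (nrow(sig))
             lapply(seq_len(nrow(sig)), function(i)
               list(sign = sig$sign[i], t_start = sig$t_start[i],
                    t_end = sig$t_end[i], cluster_sum = sig$cluster_sum[i],
                    p = sig$p[i]))
           else list())
    }),
    behavior = lapply(seq_len(nrow(behavior)), function(i)
      as.list(behavior[i, ]))
  )
  if (config$correlations)
    summary$correlations <- lapply(names(correlation_results),
                                   function(nm) {
      cl <- correlation_results[[nm]]$clusters
      list(condition = nm, n_clusters = nrow(cl),
           n_significant = sum(cl$significant))
    })
  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, waves = waves,
                 cluster_results = cluster_results,
                 correlation_results = correlation_results,
                 behavior = behavior, behavior_table = behavior_table,
                 sequence = seq, surprise = s))
}

#' Family-wise error rate of the cluster test under null simulations
#'
#' Simulates many datasets from the synthetic study generator with all MMN
#' gains at zero (so condition differences are pure noise), runs the paired
#' spatiotemporal cluster permutation test on each, and reports the
#' fraction of datasets with at least one significant cluster - a
#' Monte-Carlo estimate of the family-wise false-positive rate, which
#' max-statistic cluster correction should keep at or below the test
#' level.
#'
#' @param n_datasets number of simulated null datasets (default 500).
#' @param n_subjects subjects per dataset (default 12).
#' @param n_channels montage size: the first `n_channels` channels of
#'   [default_montage()] (default 16).
#' @param n_times epoch samples at 250 Hz starting at -0.148 s
#'   (default 128).
#' @param n_events events in the (single-run) stimulus sequence each
#'   dataset shares (default 48: large enough for stable per-subject MMN
#'   waves, small enough to keep the sweep desk-scale).
#' @param n_permutations permutations per test (default 500).
#' @param alpha significance level of each test (default 0.05).
#' @param seed global seed for the sweep (default 1).
#' @return list: `fraction` (datasets with >= 1 significant cluster),
#'   `hits` (logical per dataset), `n_datasets`, plus the shared sequence.
#' @export
cluster_fwer_sim <- function(n_datasets = 500, n_subjects = 12,
                             n_channels = 16, n_times = 128,
                             n_events = 48, n_permutations = 500,
                             alpha = 0.05, seed = 1) {
  montage <- default_montage()[seq_len(n_channels), , drop = FALSE]
  rate <- 250
  k0 <- ceiling(-0.15 * rate - 1e-9)
  window <- c(-0.15, (k0 + n_times - 0.5) / rate)
  seq <- generate_sequence(sequence_config(n_events_per_run = n_events,
                                           n_runs = 1,
                                           seed = derive_seed(seed, 17L)))
  s <- surprise_series(seq)
  adjacency <- build_adjacency(montage)
  ctcfg <- cluster_config(n_permutations = n_permutations, alpha = alpha)
  hits <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    sim <- simulation_config(n_subjects = n_subjects,
                             conditions = c(a = 0, b = 0),
                             montage = montage,
                             epoch_window = window,
                             seed = derive_seed(seed, 100L + d))
    eps <- simulate_epochs(seq, s, sim)
    waves_a <- lapply(eps, function(e) mmn_differential(e$a, seq))
    waves_b <- lapply(eps, function(e) mmn_differential(e$b, seq))
    res <- cluster_permutation_test(waves_a, waves_b, mode = "paired",
                                    adjacency = adjacency, config = ctcfg,
                                    seed = derive_seed(seed, 50000L + d))
    hits[d] <- any(res$clusters$significant)
  }
  list(fraction = mean(hits), hits = hits, n_datasets = n_datasets,
       sequence = seq)
}
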