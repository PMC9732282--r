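# Independent oracles and tiny fixture builders used across the suite.
# Every oracle is a deliberately naive re-computation (loops, quadrature,
# exhaustive enumeration) kept separate from the code paths it checks.

# KL(Beta(a1,b1) || Beta(a2,b2)) by adaptive quadrature of the integrand
oracle_beta_kl <- function(a1, b1, a2, b2) {
  integrate(function(x)
    dbeta(x, a1, b1) * (dbeta(x, a1, b1, log = TRUE) -
                          dbeta(x, a2, b2, log = TRUE)),
    0, 1, rel.tol = 1e-10)$value
}

# textbook Pearson r at every (channel, time) point, one cor() at a time
oracle_pearson_map <- function(epochs, s) {
  nch <- length(epochs$channels); nt <- length(epochs$times)
  r <- matrix(NA_real_, nch, nt)
  for (i in seq_len(nch))
    for (j in seq_len(nt)) {
      x <- epochs$data[i, j, ]
      if (sd(x) > 0 && sd(s) > 0) r[i, j] <- cor(x, s)
    }
  r
}

# one-sample t over the rows of subjects x points matrices, by the formula
oracle_t_map <- function(mats) {
  S <- do.call(rbind, lapply(mats, as.vector))
  n <- nrow(S)
  t <- apply(S, 2, function(x) {
    if (sd(x) == 0) return(NA_real_)
    mean(x) / (sd(x) / sqrt(n))
  })
  matrix(t, nrow(mats[[1]]), ncol(mats[[1]]))
}

# breadth-first connected components of the signed suprathreshold set
oracle_clusters <- function(tmap, thr, adjmat, min_ch) {
  nch <- nrow(tmap); nt <- ncol(tmap)
  mask <- matrix(0L, nch, nt)
  mask[!is.na(tmap) & tmap > thr] <- 1L
  mask[!is.na(tmap) & tmap < -thr] <- -1L
  seen <- matrix(FALSE, nch, nt)
  out <- list()
  for (i in seq_len(nch)) for (j in seq_len(nt)) {
    if (mask[i, j] == 0L || seen[i, j]) next
    sgn <- mask[i, j]
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    pts <- matrix(integer(0), 0, 2)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      pts <- rbind(pts, p)
      nbrs <- list(c(p[1], p[2] - 1L), c(p[1], p[2] + 1L))
      for (i2 in which(adjmat[p[1], ])) nbrs <- c(nbrs, list(c(i2, p[2])))
      for (q in nbrs) {
        if (q[2] < 1L || q[2] > nt) next
        if (!seen[q[1], q[2]] && mask[q[1], q[2]] == sgn) {
          seen[q[1], q[2]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    out[[length(out) + 1L]] <- list(sum = sum(tmap[pts]),
                                    n_channels = length(unique(pts[, 1])),
                                    sign = sgn)
  }
  Filter(function(cl) cl$n_channels >= min_ch, out)
}

oracle_max_cluster_stat <- function(tmap, thr, adjmat, min_ch) {
  cls <- oracle_clusters(tmap, thr, adjmat, min_ch)
  if (!length(cls)) return(0)
  max(abs(vapply(cls, `[[`, numeric(1), "sum")))
}

# exhaustive sign-flip p values: enumerate all 2^n patterns, naive t maps,
# naive clustering; returns observed |sums| and p values (sorted by |sum|)
oracle_exhaustive <- function(mats, thr, adjmat, min_ch) {
  S <- do.call(rbind, lapply(mats, as.vector))
  n <- nrow(S); nch <- nrow(mats[[1]]); nt <- ncol(mats[[1]])
  tmap_for <- function(w) {
    X <- S * w
    t <- apply(X, 2, function(x)
      if (sd(x) == 0) NA_real_ else mean(x) / (sd(x) / sqrt(n)))
    matrix(t, nch, nt)
  }
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- apply(grid, 1, function(w)
    oracle_max_cluster_stat(tmap_for(w), thr, adjmat, min_ch))
  obs <- oracle_clusters(tmap_for(rep(1, n)), thr, adjmat, min_ch)
  sums <- abs(vapply(obs, `[[`, numeric(1), "sum"))
  ord <- order(sums, decreasing = TRUE)
  list(abs_sums = sums[ord],
       p = vapply(sums[ord], function(a) mean(null >= a - 1e-8), numeric(1)))
}

# Benjamini-Hochberg step-up by its definition
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= (seq_len(m) / m) * q)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# toy sequence from a pitch string, e.g. "HHHLL" -> one-run roving table
toy_sequence <- function(pitches, run = NULL, isi = 1) {
  pitch <- ifelse(strsplit(pitches, "")[[1]] == "H", "high", "low")
  n <- length(pitch)
  run <- run %||% rep(1L, n)
  run_start <- c(TRUE, run[-1] != run[-n])
  role <- ifelse(run_start | c(TRUE, pitch[-1] != pitch[-n]),
                 "deviant", "standard")
  role[run_start] <- "deviant"
  structure(data.frame(index = seq_len(n), run = run, pitch = pitch,
                       role = role,
                       train_id = cumsum(role == "deviant"),
                       onset_s = ave(seq_len(n), run, FUN = seq_along) * isi -
                         isi,
                       stringsAsFactors = FALSE),
            class = c("stimulus_sequence", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny epoch array on a fake linear montage
toy_epochs <- function(data, times = NULL, channels = NULL) {
  d <- dim(data)
  channels <- channels %||% paste0("ch", seq_len(d[1]))
  times <- times %||% seq(0, by = 0.004, length.out = d[2])
  epoch_array(data, channels, times,
              data.frame(index = seq_len(d[3])),
              positions = data.frame(channel = channels,
                                     x = seq_len(d[1]) * 0.2, y = 0),
              sampling_rate = 1 / diff(times[1:2]))
}

# small simulated study shared by several tests
small_study <- function(n_subjects = 4, n_events = 96, seed = 7,
                        conditions = c(solo = 300, other = 600,
                                       virtual = 300),
                        n_channels = 16, ...) {
  sq <- generate_sequence(sequence_config(n_events_per_run = n_events,
                                          n_runs = 1, seed = seed))
  s <- surprise_series(sq)
  montage <- default_montage()[seq_len(n_channels), ]
  sim <- simulation_config(n_subjects = n_subjects, conditions = conditions,
                           montage = montage,
                           epoch_window = c(-0.15, 0.362),
                           seed = seed + 1, ...)
  list(seq = sq, s = s, sim = sim, montage = montage,
       epochs = simulate_epochs(sq, s, sim))
}
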