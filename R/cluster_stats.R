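#' Statistic-map container (channels x time)
#'
#' @param values channels x time numeric matrix (r or t values; NA marks
#'   points where the statistic is undefined).
#' @param kind one of `"r"`, `"t_onesample"`, `"t_paired"`.
#' @param channels channel labels.
#' @param times time axis in seconds.
#' @param df degrees of freedom, where applicable.
#' @return a `stat_map` (matrix with attributes).
#' @export
stat_map <- function(values, kind, channels = rownames(values),
                     times = NULL, df = NULL) {
  if (kind == "r" && any(abs(values) > 1 + 1e-8, na.rm = TRUE))
    stop_input("r map contains values outside [-1, 1]")
  rownames(values) <- channels
  structure(values, kind = kind, channels = channels, times = times,
            df = df, class = c("stat_map", "matrix", "array"))
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Stat map (", attr(x, "kind"), "): ", nrow(x), " channels x ",
      ncol(x), " samples", sep = "")
  if (!is.null(attr(x, "df"))) cat(", df = ", attr(x, "df"), sep = "")
  cat("; range [", signif(min(x, na.rm = TRUE), 3), ", ",
      signif(max(x, na.rm = TRUE), 3), "]\n", sep = "")
  invisible(x)
}

# accept erp_wave / stat_map / plain matrix
.as_map_matrix <- function(x) {
  if (inherits(x, "erp_wave")) return(x$data)
  if (inherits(x, "stat_map")) {
    y <- unclass(x)
    attributes(y) <- list(dim = dim(y), dimnames = dimnames(y))
    return(y)
  }
  as.matrix(x)
}

#' Trial-by-trial correlation between EEG amplitude and Bayesian surprise
#'
#' Pearson correlation across trials at every (channel, time) point of the
#' epoch.  Points with zero amplitude variance (and the whole map when the
#' surprise regressor is constant) are recorded as NA, never as silent
#' zeros.
#'
#' @param epochs an [epoch_array()].
#' @param surprise numeric surprise regressor, one value per trial.
#' @return a [stat_map()] of kind `"r"` spanning the full epoch.
#' @export
trialwise_correlation <- function(epochs, surprise) {
  ntr <- nrow(epochs$trials)
  if (length(surprise) != ntr)
    stop_input("surprise length (", length(surprise),
               ") does not match trials (", ntr, ")")
  if (ntr < 3) stop_input("need at least 3 trials for a correlation map")
  s <- as.numeric(surprise)
  nch <- length(epochs$channels); nt <- length(epochs$times)
  m <- epochs$data
  dim(m) <- c(nch * nt, ntr)
  sc <- s - mean(s)
  sss <- sum(sc^2)
  if (sss <= 0) {
    warning("surprise regressor has zero variance; r undefined everywhere",
            call. = FALSE)
    r <- matrix(NA_real_, nch, nt)
  } else {
    cross <- as.vector(m %*% sc)
    mu <- rowMeans(m)
    ssx <- pmax(rowSums(m^2) - ntr * mu^2, 0)
    r <- cross / sqrt(ssx * sss)
    r[ssx <= 1e-12 * pmax(rowSums(m^2), 1)] <- NA_real_
    r <- pmin(pmax(r, -1), 1)
    dim(r) <- c(nch, nt)
  }
  stat_map(r, "r", epochs$channels, epochs$times)
}

# one-sample t over the rows of an n x P matrix; NA where sd is 0 or any
# subject is missing
.t_onesample_rows <- function(S) {
  n <- nrow(S)
  m <- colMeans(S)
  v <- (colSums(S^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  t[!is.finite(t)] <- NA_real_
  t
}

#' Group-level pointwise t map
#'
#' One-sample t against 0 of per-subject maps (e.g. correlation maps), or a
#' paired t on per-subject condition differences (e.g. MMN waves), at every
#' (channel, time) point.  df = n_subjects - 1.  Points with zero variance
#' across subjects are undefined and returned as NA.
#'
#' @param maps list of per-subject maps ([stat_map()], [erp_wave()] or
#'   plain matrices, identical shapes).
#' @param mode `"onesample"` (default; test against the constant 0) or
#'   `"paired"` (test `maps` against `maps_b` within subject).
#' @param maps_b second-condition maps for `mode = "paired"`.
#' @param fisher_z apply the Fisher z transform (atanh) before the t test;
#'   meaningful for r maps only (default FALSE: raw correlation
#'   coefficients are compared against 0).
#' @return a [stat_map()] of kind `"t_onesample"` or `"t_paired"`.
#' @export
group_t_map <- function(maps, mode = c("onesample", "paired"),
                        maps_b = NULL, fisher_z = FALSE) {
  mode <- match.arg(mode)
  mats <- lapply(maps, .as_map_matrix)
  dims <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), dims), logical(1))))
    stop_input("subject maps have mismatching shapes")
  if (mode == "paired") {
    if (is.null(maps_b)) stop_input("paired mode needs maps_b")
    matsb <- lapply(maps_b, .as_map_matrix)
    if (length(matsb) != length(mats) ||
        !all(vapply(matsb, function(m) identical(dim(m), dims), logical(1))))
      stop_input("maps_b must pair one-to-one with maps, same shapes")
  }
  if (length(mats) < 2) stop_input("need at least 2 subjects")
  if (fisher_z) {
    mats <- lapply(mats, atanh)
    if (mode == "paired") matsb <- lapply(matsb, atanh)
  }
  S <- do.call(rbind, lapply(mats, as.vector))
  if (mode == "paired")
    S <- S - do.call(rbind, lapply(matsb, as.vector))
  t <- .t_onesample_rows(S)
  dim(t) <- dims
  first <- maps[[1L]]
  stat_map(t, if (mode == "paired") "t_paired" else "t_onesample",
           channels = if (inherits(first, "erp_wave")) first$channels
                      else attr(first, "channels") %||% rownames(mats[[1L]]),
           times = if (inherits(first, "erp_wave")) first$times
                   else attr(first, "times"),
           df = length(mats) - 1L)
}

#' Cluster-test configuration
#'
#' @param n_permutations number of random permutations (default 1000); when
#'   it reaches the exhaustive count (2^n sign patterns) the test switches
#'   to exhaustive enumeration.
#' @param alpha test level in (0, 1) (default 0.05).
#' @param cluster_percentile percentile of the permutation null used as the
#'   significance cut on cluster sums (default 95).
#' @param min_adjacent_channels minimum number of distinct channels a
#'   cluster must span to be retained (default 2; single-channel blobs are
#'   discarded regardless of their mass).
#' @param cluster_forming_p pointwise two-tailed p threshold forming the
#'   suprathreshold set (default 0.05).
#' @param statistic `"max"` (default): the null is the distribution of the
#'   maximum |cluster sum| per permutation (max-statistic FWE control);
#'   `"mean"`: the mean |cluster sum| per permutation.
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(n_permutations = 1000, alpha = 0.05,
                           cluster_percentile = 95,
                           min_adjacent_channels = 2,
                           cluster_forming_p = 0.05,
                           statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  if (!(alpha > 0 && alpha < 1)) stop_input("alpha must be in (0, 1)")
  if (n_permutations < 1) stop_input("n_permutations must be >= 1")
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 cluster_percentile = cluster_percentile,
                 min_adjacent_channels = as.integer(min_adjacent_channels),
                 cluster_forming_p = cluster_forming_p,
                 statistic = statistic),
            class = "cluster_config")
}

#' Spatiotemporal cluster-based permutation test
#'
#' Pointwise group t map thresholded two-tailed at `cluster_forming_p`;
#' suprathreshold points of equal sign are grouped into spatiotemporal
#' clusters through temporal contiguity (adjacent samples, same channel)
#' and spatial adjacency (neighbouring channels, same sample); clusters
#' spanning fewer than `min_adjacent_channels` distinct channels are
#' discarded; each surviving cluster is scored by its summed t.  The null
#' distribution collects the maximum |cluster sum| per permutation, where
#' permutations flip the sign of whole subject maps (one-sample) or swap
#' the two condition labels within subject (paired; equivalent to flipping
#' the sign of the difference map).  A cluster is significant when its
#' |sum| exceeds the `cluster_percentile` of the null; its p value is the
#' permutation tail probability.  When 2^n_subjects does not exceed
#' `n_permutations`, all sign patterns are enumerated and p values are
#' exact.
#'
#' @param maps list of per-subject maps (first condition, for paired mode).
#' @param maps_b second-condition maps for paired mode.
#' @param mode `"onesample"` or `"paired"`.
#' @param adjacency an [build_adjacency()] graph covering the maps'
#'   channels.
#' @param config a [cluster_config()].
#' @param seed optional integer seed for the random permutations.
#' @param fisher_z passed to [group_t_map()].
#' @return a `cluster_result`: list with `clusters` (data.frame: sign,
#'   n_points, n_channels, time window, cluster_sum, p, significant),
#'   `members` (per-cluster data.frames of channel/time points), `t_map`,
#'   `labels`, `null` (permutation distribution), `null_cutoff`,
#'   `exhaustive`, `config`, `mode`, `n_subjects`.
#' @export
cluster_permutation_test <- function(maps, maps_b = NULL,
                                     mode = c("onesample", "paired"),
                                     adjacency, config = cluster_config(),
                                     seed = NULL, fisher_z = FALSE) {
  mode <- match.arg(mode)
  tmap <- group_t_map(maps, mode, maps_b, fisher_z = fisher_z)
  nch <- nrow(tmap); nt <- ncol(tmap)
  if (nrow(adjacency) != nch)
    stop_input("adjacency graph (", nrow(adjacency),
               " channels) does not cover the maps (", nch, " channels)")
  n <- length(maps)
  df <- n - 1L
  tcrit <- stats::qt(1 - config$cluster_forming_p / 2, df)
  adj0 <- adjacency_neighbors(adjacency, zero_based = TRUE)
  # subject-level difference/score matrix, rows = subjects
  mats <- lapply(maps, .as_map_matrix)
  if (fisher_z) mats <- lapply(mats, atanh)
  S <- do.call(rbind, lapply(mats, as.vector))
  if (mode == "paired") {
    matsb <- lapply(maps_b, .as_map_matrix)
    if (fisher_z) matsb <- lapply(matsb, atanh)
    S <- S - do.call(rbind, lapply(matsb, as.vector))
  }
  exhaustive <- 2^n <= config$n_permutations
  if (exhaustive) {
    message("exhaustive enumeration: 2^", n, " = ", 2^n,
            " sign patterns <= n_permutations = ", config$n_permutations)
    E <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    dimnames(E) <- NULL
  } else {
    if (!is.null(seed)) set.seed(seed)
    E <- matrix(sample(c(-1, 1), config$n_permutations * n, replace = TRUE),
                config$n_permutations, n)
  }
  SS <- colSums(S^2)
  M <- E %*% S / n
  V <- sweep(-n * M^2, 2, SS, `+`) / (n - 1)
  V[V < 0] <- 0
  Tm <- M / sqrt(V / n)
  Tm[!is.finite(Tm)] <- NA_real_
  null <- cluster_null_stats_cpp(Tm, nch, nt, tcrit, adj0,
                                 config$min_adjacent_channels,
                                 config$statistic == "mean")
  cutoff <- stats::quantile(null, config$cluster_percentile / 100,
                            names = FALSE)
  comp <- cluster_components_cpp(unclass(tmap), tcrit, adj0)
  keep <- which(comp$n_channels >= config$min_adjacent_channels)
  times <- attr(tmap, "times") %||% seq_len(nt)
  channels <- attr(tmap, "channels") %||% rownames(tmap) %||%
    as.character(seq_len(nch))
  clusters <- data.frame(sign = integer(0), n_points = integer(0),
                         n_channels = integer(0), t_start = numeric(0),
                         t_end = numeric(0), cluster_sum = numeric(0),
                         p = numeric(0), significant = logical(0))
  members <- list()
  if (length(keep)) {
    ord <- keep[order(abs(comp$sum[keep]), decreasing = TRUE)]
    tol <- 1e-8
    rows <- lapply(ord, function(k) {
      pts <- which(comp$labels == k, arr.ind = TRUE)
      a <- abs(comp$sum[k])
      p <- if (exhaustive) mean(null >= a - tol)
      else (1 + sum(null >= a - tol)) / (1 + length(null))
      data.frame(sign = comp$sign[k], n_points = nrow(pts),
                 n_channels = comp$n_channels[k],
                 t_start = min(times[pts[, 2]]),
                 t_end = max(times[pts[, 2]]),
                 cluster_sum = comp$sum[k], p = p,
                 significant = a > cutoff)
    })
    clusters <- do.call(rbind, rows)
    rownames(clusters) <- NULL
    members <- lapply(ord, function(k) {
      pts <- which(comp$labels == k, arr.ind = TRUE)
      data.frame(channel = channels[pts[, 1]], time = times[pts[, 2]],
                 stringsAsFactors = FALSE)
    })
  }
  structure(list(clusters = clusters, members = members, t_map = tmap,
                 labels = comp$labels, null = null, null_cutoff = cutoff,
                 exhaustive = exhaustive, config = config, mode = mode,
                 n_subjects = n, t_critical = tcrit),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster-based permutation test (", x$mode, ", ",
      if (x$exhaustive) "exhaustive" else
        paste0(length(x$null), " permutations"),
      ", ", x$n_subjects, " subjects)\n", sep = "")
  cat("  cluster-forming |t| > ", signif(x$t_critical, 4),
      "; null ", x$config$cluster_percentile, "th percentile = ",
      signif(x$null_cutoff, 4), "\n", sep = "")
  if (nrow(x$clusters) == 0) {
    cat("  no clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}
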