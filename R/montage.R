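#' Default 32-channel 10-20 montage
#'
#' A 32-channel superset of the international 10-20 system with approximate
#' 2-D scalp-projection coordinates (head radius 1, x towards the right ear,
#' y towards the nasion).  The set covers every frontal, central, parietal
#' and occipital site used in typical roving-oddball MMN reports (Fp1, Fpz,
#' Fp2, F7, F3, Fz, F4, F8, FC5, FC1, FCz, FC2, T7, C3, Cz, CP5, CP1, CP2,
#' CP6, P7, P3, Pz, P4, POz, Oz, O2, ...).
#'
#' @param channels optional character vector restricting the montage to a
#'   subset of channel labels (order preserved as given).
#' @return a data.frame with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' head(default_montage())
#' default_montage(c("Fz", "Cz", "Pz"))
default_montage <- function(channels = NULL) {
  m <- data.frame(
    channel = c("Fp1", "Fpz", "Fp2",
                "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FCz", "FC2", "FC6",
                "T7", "C3", "Cz", "C4", "T8",
                "CP5", "CP1", "CPz", "CP2", "CP6",
                "P7", "P3", "Pz", "P4", "P8",
                "POz", "O1", "Oz", "O2"),
    x = c(-0.28, 0, 0.28,
          -0.73, -0.37, 0, 0.37, 0.73,
          -0.60, -0.20, 0, 0.20, 0.60,
          -0.90, -0.45, 0, 0.45, 0.90,
          -0.60, -0.20, 0, 0.20, 0.60,
          -0.73, -0.37, 0, 0.37, 0.73,
          0, -0.28, 0, 0.28),
    y = c(0.85, 0.90, 0.85,
          0.55, 0.50, 0.45, 0.50, 0.55,
          0.27, 0.23, 0.225, 0.23, 0.27,
          0, 0, 0, 0, 0,
          -0.27, -0.23, -0.225, -0.23, -0.27,
          -0.55, -0.50, -0.45, -0.50, -0.55,
          -0.675, -0.85, -0.90, -0.85),
    stringsAsFactors = FALSE
  )
  if (!is.null(channels)) {
    missing <- setdiff(channels, m$channel)
    if (length(missing))
      stop_input("unknown channel(s): ", paste(missing, collapse = ", "))
    m <- m[match(channels, m$channel), , drop = FALSE]
    rownames(m) <- NULL
  }
  m
}

#' Build an electrode adjacency graph from montage positions
#'
#' Two channels are neighbours when their 2-D scalp distance does not exceed
#' a threshold.  By default the threshold is `multiplier` times the median
#' nearest-neighbour distance of the montage, which for regular 10-20-style
#' layouts connects each site to its immediate ring of neighbours.
#'
#' @param montage data.frame with columns `channel`, `x`, `y`.
#' @param radius explicit distance threshold; overrides `multiplier`.
#' @param multiplier scale factor on the median nearest-neighbour distance
#'   (default 1.3).
#' @return an `adjacency_graph`: a symmetric, irreflexive logical matrix
#'   with channel dimnames and attributes `channels` and `threshold`.
#' @export
#' @examples
#' adj <- build_adjacency(default_montage())
#' sum(adj["Fz", ])  # number of neighbours of Fz
build_adjacency <- function(montage, radius = NULL, multiplier = 1.3) {
  if (!all(c("channel", "x", "y") %in% names(montage)))
    stop_input("montage must have columns channel, x, y")
  if (nrow(montage) < 2)
    stop_input("need at least 2 channels with positions")
  bad <- montage$channel[!is.finite(montage$x) | !is.finite(montage$y)]
  if (length(bad))
    stop_input("missing positions for channel(s): ",
               paste(bad, collapse = ", "))
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  dimnames(d) <- list(montage$channel, montage$channel)
  if (is.null(radius)) {
    nn <- apply(d + diag(Inf, nrow(d)), 1, min)
    radius <- multiplier * stats::median(nn)
  }
  a <- d <= radius
  diag(a) <- FALSE
  structure(a, channels = montage$channel, threshold = radius,
            class = c("adjacency_graph", class(a)))
}

#' Neighbour index list of an adjacency graph
#'
#' @param adjacency an `adjacency_graph` (or plain logical matrix).
#' @param zero_based return 0-based indices (used by the compiled cluster
#'   kernel); default FALSE.
#' @return list of integer vectors, one per channel.
#' @export
adjacency_neighbors <- function(adjacency, zero_based = FALSE) {
  off <- if (zero_based) 1L else 0L
  lapply(seq_len(nrow(adjacency)),
         function(i) which(adjacency[i, ]) - off)
}
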