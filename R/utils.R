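`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

# 32-bit FNV-1a over a character string, returned as 8 hex digits.  Used to
# fingerprint configurations in output sidecars; arithmetic is done in
# doubles split at 16 bits so products stay exact.
#' @noRd
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  two32 <- 2^32
  for (b in bytes) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor for non-negative doubles < 2^32 (base bitwXor is 32-bit signed)
#' @noRd
bitwXor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

# deterministic stage seeds derived from a global seed (kept below 2^31)
#' @noRd
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1013904223 + 7919 * stage) %% 2147483647L
}

#' @noRd
config_fingerprint <- function(config) {
  fnv1a_hash(paste(deparse(config), collapse = ""))
}
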