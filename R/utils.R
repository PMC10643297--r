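# Small shared helpers: clamping, hashing, truncated-normal draws.

#' Clamp values to an interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds (recycled).
#' @return `x` with values outside `[lo, hi]` moved to the nearest bound.
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 32-bit FNV-1a over the UTF-8 bytes of a string. Implemented with split
# multiplication so intermediates stay below 2^53 (exact in doubles).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h_hi <- floor(h / 65536)
    h_lo <- h - h_hi * 65536
    h <- ((h_hi * 16777619) %% 65536) * 65536 + h_lo * 16777619
    h <- h %% 4294967296
  }
  h
}

# bitwXor for doubles holding 32-bit unsigned values (bitwXor needs ints)
bitwXor32 <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

#' Derive a deterministic RNG seed for one simulation stream
#'
#' Hashes the master seed together with the scenario name and replication
#' index, so a stream's seed never depends on which other scenarios or
#' replications are in the batch.
#'
#' @param master_seed integer master seed.
#' @param scenario scenario name (character scalar).
#' @param rep replication index (integer, 1-based).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
stream_seed <- function(master_seed, scenario, rep) {
  key <- paste(master_seed, scenario, rep, sep = "/")
  as.integer(fnv1a32(key) %% 2147483645 + 1)
}

# Truncated-normal draws by inverse CDF; degenerate intervals collapse to mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  degenerate <- sd <= 0 | lo >= hi
  if (all(degenerate)) return(rep(mean, length.out = n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  out <- stats::qnorm(u, mean, sd)
  out <- clamp(out, lo, hi)
  if (any(degenerate)) out[degenerate] <- rep(mean, length.out = n)[degenerate]
  out
}

# Canonical hash of an R config-like object: keys sorted recursively, then
# deparsed and FNV-hashed. Stable across key reordering.
canonical_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm)) v <- v[order(nm)]
      lapply(v, canon)
    } else v
  }
  h <- fnv1a32(paste(deparse(canon(x)), collapse = ""))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
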