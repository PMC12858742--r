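#' Derive a child seed from a master seed and a stream key
#'
#' All pipeline entry points take a single integer seed and fan it out to
#' per-stage random streams through this function, so that adding draws to one
#' subsystem does not perturb the sampling of another. The derivation is a
#' small multiplicative congruential mix of the seed with a hash of the key;
#' it is stable across platforms because all arithmetic stays below 2^53.
#'
#' @param seed integer master seed.
#' @param key character stream label, e.g. `"config:12"`.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% m
  as.integer(((seed %% m) * 48271 + h * 69621 + 11) %% m)
}

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a character string, returned as a hex string. Used for
# config digests in run manifests (stable, dependency-free).
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  # 32-bit FNV-1a carried out in doubles (exact below 2^53)
  h <- 2166136261
  for (v in utf8ToInt(x)) {
    h <- bitwXor_dbl(h, v)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of two non-negative doubles representing 32-bit integers
bitwXor_dbl <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    ra <- a %% 2
    rb <- b %% 2
    if (ra != rb) r <- r + p
    a <- (a - ra) / 2
    b <- (b - rb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}
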