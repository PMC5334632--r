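# Internal helpers shared across modules.

.apa_cache <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signed relative mass deviation in parts per million
#'
#' @param observed Observed m/z.
#' @param expected Expected (calculated) m/z.
#' @return Signed deviation `(observed - expected) / expected * 1e6`.
#' @export
ppm_deviation <- function(observed, expected) {
  (observed - expected) / expected * 1e6
}

# absolute m/z tolerance corresponding to a ppm tolerance at a given m/z
ppm_to_da <- function(mz, ppm) mz * ppm * 1e-6

# Deterministic 31-bit polynomial string hash. Used to derive reproducible
# per-sample / per-compound quantities that must not depend on R's RNG state.
stable_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  # finalization rounds spread small input differences across the range
  for (i in 1:3) h <- (h * 69069 + 1) %% 2147483647
  as.integer(h)
}

# Derive a child seed (< 2^31) from a user seed and a salt string.
derive_seed <- function(seed, salt) {
  as.integer((abs(as.numeric(seed)) * 7919 + stable_hash(salt)) %% 2147483647)
}

# mass difference between 13C and 12C; isotope spacing per charge unit
C13_SPACING <- 1.003355

# natural abundance of 13C used by the binomial isotope model
C13_ABUNDANCE <- 0.0107
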