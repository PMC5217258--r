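# Seeded substreams.
#
# Reproducibility contract: every stochastic routine takes an integer seed
# and derives independent substreams with `substream_seed`, so that (a) a
# fixed seed reproduces results exactly, (b) per-unit streams (patient i,
# bootstrap replicate b) do not depend on how many other units are drawn,
# and (c) package routines never disturb the caller's RNG state.
#
# Linearly related seeds fed to set.seed() give measurably correlated first
# draws (Mersenne-Twister seeding is not an avalanche function), which is
# enough to bias coefficient-recovery simulations.  The substream seed is
# therefore a proper 32-bit avalanche hash (lowbias32) of (seed, i, phase),
# implemented in exact double arithmetic.

# xor of two 32-bit values held in doubles
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

# (a * b) mod 2^32 without losing precision
mul32 <- function(a, b) {
  a1 <- a %/% 65536
  a0 <- a %% 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
}

# lowbias32 avalanche hash (Wellons), bijective on 32 bits
lowbias32 <- function(h) {
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2135587861)  # 0x7feb352d
  h <- xor32(h, h %/% 32768)
  h <- mul32(h, 2216992491)  # 0x846ca68b
  xor32(h, h %/% 65536)
}

# Derived seed for substream (i, phase) of a global seed; < 2^31.
substream_seed <- function(seed, i, phase = 0L) {
  h <- lowbias32((as.double(seed) %% 4294967296))
  h <- lowbias32((h + as.double(i)) %% 4294967296)
  h <- lowbias32((h + as.double(phase) + 2654435769) %% 4294967296)
  as.integer(h %% 2147483629)
}

# Set the RNG to a given seed, returning the previous state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

# Restore RNG state captured by local_rng.
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
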