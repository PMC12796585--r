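# Keyed FNV-1a hashing in pure R. 32-bit arithmetic is done on doubles:
# (a * b) mod 2^32 is exact when computed via 16-bit limbs, since every
# intermediate product stays below 2^53.

FNV_PRIME_32 <- 16777619
FNV_BASIS_32 <- 2166136261

mul_mod32 <- function(a, b) {
  a_hi <- floor(a / 65536)
  a_lo <- a - a_hi * 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
}

xor32 <- function(a, b) {
  # bitwXor needs signed 32-bit ints; map [0, 2^32) onto that range and back
  ai <- if (a >= 2147483648) as.integer(a - 4294967296) else as.integer(a)
  bi <- if (b >= 2147483648) as.integer(b - 4294967296) else as.integer(b)
  r <- bitwXor(ai, bi)
  if (r < 0) r + 4294967296 else as.numeric(r)
}

fnv1a32 <- function(bytes, basis = FNV_BASIS_32) {
  h <- basis
  for (b in bytes) h <- mul_mod32(xor32(h, b), FNV_PRIME_32)
  h
}

# hex rendering of a 32-bit value held in a double
hex32 <- function(h) sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))

#' Keyed 64-bit FNV-1a hash of a character vector
#'
#' Two chained 32-bit FNV-1a passes over `salt || ":" || x`, formatted as 16
#' lowercase hex characters. Deterministic for a fixed `(x, salt)` pair.
#'
#' @param x character vector to hash.
#' @param salt non-empty secret string keying the hash.
#' @return character vector of 16-hex-character digests.
#' @keywords internal
keyed_hash <- function(x, salt) {
  stopifnot(is.character(x), is.character(salt), length(salt) == 1L)
  if (!nzchar(salt)) {
    abort("`salt` must be a non-empty string: an unkeyed pseudonym is a disclosure risk.")
  }
  vapply(x, function(id) {
    bytes <- as.integer(charToRaw(paste0(salt, ":", id)))
    h1 <- fnv1a32(bytes)
    # chain: second pass keyed by the first digest
    h2 <- fnv1a32(bytes, basis = xor32(FNV_BASIS_32, h1))
    paste0(hex32(h1), hex32(h2))
  }, character(1), USE.NAMES = FALSE)
}

# Small deterministic integer stream derived from a user seed; used to give
# each simulated patient its own substream. Always < 2^31.
derive_seed <- function(seed, key) {
  bytes <- as.integer(charToRaw(paste0(seed, "/", key)))
  as.integer(fnv1a32(bytes) %% 2147483647)
}
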