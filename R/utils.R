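# Shared numeric helpers. Conventions fixed package-wide:
# rounding is half-away-from-zero (not R's banker's rounding), pixel
# coordinates are 0-based with origin top-left and x = column.

# round() uses round-half-to-even; image quantization needs half-away-from-zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

quantize8 <- function(x) as.integer(clip8(round_half_away(x)))

# Run `code` under a private RNG stream: the global .Random.seed is
# saved/restored so simulation calls never perturb user RNG state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# FNV-1a 32-bit hash over a character scalar; used to stamp output
# artifacts with a short configuration fingerprint.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double to avoid
    # 32-bit overflow in bitwXor
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by the FNV prime 16777619, done in two halves
    # to stay inside double precision
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  # format as hex from the two 16-bit halves (h is a double)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

condition_number <- function(m) {
  d <- svd(m, nu = 0, nv = 0)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}
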