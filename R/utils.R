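#' @keywords internal
"_PACKAGE"

# Digest of a raw vector (md5 over the exact bytes). Used for parameter
# bit-exactness and manifest digests; comparisons are always on the raw
# digest string, never on rounded displays.
raw_digest <- function(bytes) {
  stopifnot(is.raw(bytes))
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf), add = TRUE)
  writeBin(bytes, tf)
  unname(tools::md5sum(tf))
}

string_digest <- function(x) {
  raw_digest(charToRaw(enc2utf8(x)))
}

# Canonical little-endian byte serialization of a double vector; the fixed
# traversal order is the vector order itself.
serialize_params <- function(params) {
  if (is.raw(params)) return(params)
  stopifnot(is.numeric(params))
  writeBin(as.double(params), raw(), size = 8L, endian = "little")
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream (the harness must not leak seed state between runs).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# OS entropy, explicitly outside any seeded RNG stream: set.seed() cannot
# tame it. Raw bytes from the operating system's entropy provider.
urandom_bytes <- function(n) {
  con <- file("/dev/urandom", "rb", raw = TRUE)
  on.exit(close(con), add = TRUE)
  readBin(con, "raw", n = n)
}

# n doubles in [0, 1) from OS entropy (53 random mantissa bits each).
urandom_runif <- function(n) {
  b <- urandom_bytes(8L * n)
  m <- matrix(as.double(as.integer(b)), nrow = 8L)
  hi <- m[1, ] * 2^24 + m[2, ] * 2^16 + m[3, ] * 2^8 + m[4, ]     # 32 bits
  lo <- m[5, ] * 2^13 + m[6, ] * 2^5 + m[7, ] %/% 8               # 21 bits
  (hi * 2^21 + lo) / 2^53
}

# A permutation of seq_len(n) drawn from OS entropy.
urandom_permutation <- function(n) {
  order(urandom_runif(n), seq_len(n))
}

# Standard normals from OS entropy (Box-Muller on urandom uniforms).
urandom_normal <- function(n) {
  m <- ceiling(n / 2)
  u1 <- pmax(urandom_runif(m), 2^-53)
  u2 <- urandom_runif(m)
  r <- sqrt(-2 * log(u1))
  z <- c(r * cos(2 * pi * u2), r * sin(2 * pi * u2))
  z[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

detml_stop <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "detml_error")))
}
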