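# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed and a stage label.
# Keeps results < 2^31 so they remain valid R integers.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- fnv1a32(paste0(label, ":", as.integer(seed)))
  as.integer(h %% 2147483647)
}

# FNV-1a 32-bit hash, done in double arithmetic (exact below 2^53).
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of a 32-bit value (double) with a byte
bitwXor_dbl <- function(h, b) {
  low <- h %% 256
  h - low + bitwXor(as.integer(low), as.integer(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursively drop S3 classes so a config serialises as plain JSON.
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

stop2 <- function(...) stop(..., call. = FALSE)

assert_prob <- function(p, name = "p", open = TRUE) {
  if (!is.numeric(p) || anyNA(p)) stop2(name, " must be numeric and non-NA")
  if (open) {
    if (any(p <= 0 | p >= 1)) stop2(name, " must lie strictly in (0, 1)")
  } else if (any(p < 0 | p > 1)) stop2(name, " must lie in [0, 1]")
  invisible(p)
}
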