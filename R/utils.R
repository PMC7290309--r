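# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 16807 + 1
  as.integer(s %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Integer translation of a matrix with zero fill. `offset = c(drow, dcol)`
# moves content down/right for positive values.
shift_matrix <- function(m, offset, fill = 0) {
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- max(1, 1 - dr):min(h, h - dr)
  src_c <- max(1, 1 - dc):min(w, w - dc)
  if (length(src_r) < 1 || length(src_c) < 1) return(out)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Quantize a [0,1] float matrix to 8-bit integers in [0,255].
quantize_8bit <- function(x) {
  matrix(as.integer(round(clamp(x, 0, 1) * 255)), nrow(x), ncol(x))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
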