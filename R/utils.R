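# Internal helpers shared across modules.

# Classed condition so callers can distinguish validation failures from
# numerical failures programmatically.
palmbp_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("palmbp_", class), "palmbp_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_invalid <- function(msg) palmbp_stop(msg, "invalid_argument")

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `seed` must be a single finite number below 2^31.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a style 32-bit rolling hash over a string, done in double arithmetic
# (exact below 2^53). Used for configuration fingerprints; it is a
# consistency token, not a cryptographic digest.
string_fingerprint <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # multiply by the FNV prime modulo 2^32, via 16-bit split
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) %% 2^32 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
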