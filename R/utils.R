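# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All package generators route their randomness through this, so a single
# explicit seed reproduces any synthetic data set bit for bit.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# FNV-1a over a character scalar; used to fingerprint run configurations in
# output metadata so that identical configs produce identical headers.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay within
    # double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536 * 65536 + h0 * 16777619) %% 4294967296
  }
  # h can exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
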