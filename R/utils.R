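# internal helpers shared across modules

# 1 nC = 1000 uA*us (= 1000 pC); all charge arithmetic runs in uA*us
NC_TO_UAUS <- 1000

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a private RNG stream; the caller's RNG state is untouched.
# `seed` = NULL means: use (and advance) the global stream.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Truncated-normal sampler via inverse-CDF; vectorized over n.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    # tail so extreme the window has no mass; fall back to nearest bound
    return(rep(if (mean < lower) lower else upper, n))
  }
  qnorm(runif(n, plo, phi), mean, sd)
}

# FNV-1a 32-bit hash of a character scalar, hex string; used to fingerprint
# configurations in logs without an external digest dependency.
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit multiply by the FNV prime 16777619 = 2^24 + 403, split so every
    # intermediate stays below 2^53
    h <- ((h %% 256) * 16777216 + h * 403) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_input(what, ": missing column(s) ", paste(missing, collapse = ", "))
  invisible(df)
}
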