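# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the generator seeded at `seed`, then restores whatever
#' global RNG state existed before the call, so package functions never
#' disturb a user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar; used only for provenance tags.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, split to stay in
    # double precision
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Truncated normal on [0, 1] by inverse-CDF; degenerate sd collapses to the
# clamped mean.
rtnorm01 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(min(max(mean, 0), 1), n))
  lo <- stats::pnorm((0 - mean) / sd)
  hi <- stats::pnorm((1 - mean) / sd)
  u <- stats::runif(n, lo, hi)
  mean + sd * stats::qnorm(u)
}
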