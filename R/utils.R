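#' Evaluate an expression with a temporary RNG seed
#'
#' All randomized operations in the package funnel through this helper so a
#' single integer seed fully determines results without disturbing the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Keeps independent random streams (per replicate, per sample, per fold)
#' reproducible from one user-supplied seed. Result lies in `[1, 2^31 - 2]`,
#' safe for R's 32-bit integer seeds.
#'
#' @param seed parent integer seed.
#' @param ... integers or strings identifying the stream.
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, ...) {
  as.integer(str_hash(paste(c(seed, ...), collapse = "/")) %% 2147483646) + 1L
}

# deterministic 31-bit polynomial hash of a character scalar (not crypto;
# used for seed streams and human-readable fingerprints)
str_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x01")))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  h
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
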