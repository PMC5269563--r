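# Internal helpers: classed conditions, seeded-RNG scoping, and a portable
# string hash used by the deterministic mock affinity predictor and for
# deriving per-tumor random substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("neoepitree_format_error", "neoepitree_error")))
}

#' @noRd
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("neoepitree_validation_error", "neoepitree_error")))
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards. With `seed = NULL` the expression uses the ambient
#' RNG stream unchanged.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_validation("seed must be a single number, got %s", deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible 31-bit sub-seed from a run seed and a stream index,
# so per-tumor streams are independent of iteration order.
#' @noRd
derive_seed <- function(seed, index) {
  m <- 2147483647
  v <- (as.numeric(seed) %% m) * 48271 + 97 * as.numeric(index) + 13
  as.integer(v %% m)
}

# Deterministic polynomial hash of strings, folded modulo 2^31 - 1 using
# exact double arithmetic (every intermediate stays below 2^53, so results
# are platform independent). Strings are right-padded to a fixed width of
# 64 characters so the value never depends on how calls are batched.
#' @noRd
str_hash <- function(x, salt = 0) {
  m <- 2147483647
  width <- 32L
  codes <- lapply(as.character(x), utf8ToInt)
  if (any(lengths(codes) > width))
    stop_validation("str_hash input longer than %d characters", width)
  mat <- vapply(codes, function(z) c(z, rep(0, width - length(z))),
                numeric(width))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = width)
  h <- rep((5381 + as.numeric(salt)) %% m, ncol(mat))
  for (i in seq_len(width)) h <- (h * 131 + mat[i, ]) %% m
  h
}

# Uniform-ish deviate in (0, 1) from a string; `salt` yields independent
# channels for the same key. A polynomial hash is linear in its input, so
# two strings differing at one character would keep a deterministic hash
# offset; re-hashing the decimal digits of the first round is nonlinear
# and breaks that correlation (needed because mutant and wild-type
# peptide windows differ at exactly one residue).
#' @noRd
hash_unit <- function(x, salt = 0) {
  h1 <- str_hash(x, salt)
  h2 <- str_hash(sprintf("%010.0f", h1), salt + 7777)
  (h2 + 0.5) / 2147483647
}

# Round half away from zero to `digits` decimals (printed-percent convention;
# base round() is banker's rounding).
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Canonical mutation key
#'
#' The `chrom:pos:ref:alt` string identifying a variant throughout the
#' package (panel lookup, clone assignment, epitope calls).
#'
#' @param chrom,pos,ref,alt Variant fields (vectorised).
#' @return Character vector of keys.
#' @export
mutation_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
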