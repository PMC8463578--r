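# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# seed = NULL means "use the current RNG stream" (no-op wrapper).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_binary <- function(x, what = "input") {
  if (!is.numeric(x) && !is.logical(x)) stopf("%s must be numeric", what)
  if (anyNA(x) || !all(x == 0 | x == 1)) stopf("%s must be binary (0/1)", what)
  invisible(TRUE)
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(TRUE)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Numerically stable column-wise softmax of a C x B matrix.
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
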