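# Internal helpers shared across modules.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and a stage label, staying within
# the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0L, 1L))
}

assert_mask <- function(m, arg = "mask") {
  if (!is_binary_mask(m)) {
    abort(sprintf("`%s` must be a binary (0/1) matrix.", arg))
  }
  invisible(m)
}

assert_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must have identical dimensions (%s vs %s).",
                  what, paste(dim(a), collapse = "x"),
                  paste(dim(b), collapse = "x")))
  }
  invisible(NULL)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

clip01 <- function(x) pmin(pmax(x, 0), 1)
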