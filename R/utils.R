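# Small shared helpers.

# Derive a reproducible child seed from a master seed and a stream index.
# Keeps every derived seed a valid 32-bit integer so adding a variable to
# the schema never perturbs the random stream of another variable.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Coerce a counts input (matrix, table or data frame of counts) to a
# plain non-negative numeric matrix with dimnames preserved.
as_count_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    rn <- NULL
    if (is.character(x[[1]]) || is.factor(x[[1]])) {
      rn <- as.character(x[[1]])
      x <- x[, -1, drop = FALSE]
    }
    x <- as.matrix(x)
    if (!is.null(rn)) rownames(x) <- rn
  }
  if (inherits(x, "table")) x <- unclass(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix, table or data frame of counts.", arg))
  }
  if (any(x < 0) || any(!is.finite(x))) {
    abort(sprintf("`%s` must contain finite non-negative counts.", arg))
  }
  x
}

check_lengths_equal <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("Vectors must have equal length (got %d and %d).",
                  length(x), length(y)))
  }
}
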