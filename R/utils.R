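## Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage seed from a base seed; stays inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483587)
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

# Flatten a 3D array to the vector of in-mask values.
mask_values <- function(map, mask) {
  as.vector(map)[as.vector(mask)]
}

# Embed a vector of in-mask values back into a 3D array (0 elsewhere).
embed_in_mask <- function(values, mask, fill = 0) {
  out <- array(fill, dim = dim(mask))
  out[mask] <- values
  out
}

check_same_dim <- function(a, b, what = "maps") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share one grid: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}
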