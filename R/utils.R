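# Internal helpers shared across modules.

# Round half away from zero. Labels are categorical, so nearest-voxel lookup
# needs a deterministic rule that does not depend on R's banker's rounding.
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Generators must be pure functions of their
# spec, so they must not consume the global stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 0-based pixel coordinates -> 1-based matrix indices, with bounds check.
# A LabelMap is stored height x width; pixel (x, y) lives at [y + 1, x + 1].
stopifnotScalarCount <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}
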