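# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package-level randomness goes
# through this so that user RNG state is never disturbed.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(value, field, min = 0) {
  if (length(value) != 1 || !is.numeric(value) || is.na(value) ||
      value != floor(value) || value < min) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(value)
}

check_number <- function(value, field, min = -Inf, max = Inf) {
  if (length(value) != 1 || !is.numeric(value) || is.na(value) ||
      value < min || value > max) {
    stop_field(field, sprintf("must be a single number in [%s, %s]",
                              format(min), format(max)))
  }
  as.numeric(value)
}
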