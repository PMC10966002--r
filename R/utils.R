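# Internal helpers shared across modules.

# Derive a deterministic 32-bit sub-seed from a master seed and a stream
# label, so adding a new generator never perturbs existing random streams.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  bytes <- utf8ToInt(as.character(stream))
  h <- as.double(seed %% 2147483647)
  for (b in bytes) h <- (h * 69069 + b) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, stream, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(x)
}

assert_columns <- function(data, cols, context = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      context, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Canonical string id of a variable subset (sorted, "+"-joined; empty = "(none)")
subset_id <- function(members) {
  if (length(members) == 0) return("(none)")
  paste(sort(members), collapse = "+")
}
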