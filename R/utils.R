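# Internal helpers shared across modules.

# Evaluate `code` under a locally-seeded RNG without disturbing the caller's
# RNG state. seed = NULL runs `code` with the ambient RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed so independent
# generators invoked with the same seed do not share a stream.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  # double arithmetic (exact below 2^53) avoids 32-bit integer overflow
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}

stop_pf <- function(..., class) {
  stop(structure(
    class = c(class, "promoterflux_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_matrix_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_pf(name, " must be a numeric matrix", class = "pf_bad_input")
  }
  if (!all(is.finite(x))) {
    stop_pf(name, " contains non-finite pixel values", class = "pf_bad_input")
  }
  invisible(x)
}
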