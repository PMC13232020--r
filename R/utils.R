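#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' seeded package internals never perturb user-level random streams.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return Value of \code{expr}.
#' @keywords internal
#' @export
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# derive a bounded child seed from a base seed and a stream index
.childSeed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 1009) %% 2147483647
}
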