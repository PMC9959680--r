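#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points funnel through this so a seed argument makes
# the whole call reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_pq <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "pyrroqsar_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
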