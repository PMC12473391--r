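# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals do not
#' disturb the caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
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

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

checkRange <- function(x, name, lo = -Inf, hi = Inf) {
  stopIfNot(is.numeric(x) && length(x) %in% c(1L, 2L) && all(is.finite(x)),
            sprintf("'%s' must be finite numeric", name))
  if (length(x) == 2L)
    stopIfNot(x[1] <= x[2], sprintf("'%s' must be an ordered (low, high) pair", name))
  stopIfNot(all(x >= lo) && all(x <= hi),
            sprintf("'%s' must lie within [%g, %g]", name, lo, hi))
  x
}

# deterministic config fingerprint used in provenance headers
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
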