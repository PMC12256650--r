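#' @keywords internal
"_PACKAGE"

## NULL coalescing used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' All stochastic operations in the package take an explicit seed and run
#' through this helper, so they never disturb (or depend on) the caller's
#' global RNG state.
#'
#' @param seed single integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## lightweight logger; silenced via options(dolloscan.quiet = TRUE)
log_msg <- function(...) {
  if (!isTRUE(getOption("dolloscan.quiet", FALSE))) {
    message("[dolloscan] ", ...)
  }
  invisible(NULL)
}
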