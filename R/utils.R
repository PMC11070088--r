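#' @importFrom rlang abort warn %||% .data
#' @importFrom stats lm anova coef vcov pt ptukey rexp rnorm rpois runif
#'   sd setNames complete.cases quantile resid
#' @importFrom utils head tail
NULL

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so library internals never perturb user-level reproducibility.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
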