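## Canonical category codes used across the package.
## Stimulus conditions: the catch condition anchors the decision space at the
## origin and is always listed last.
STIMULI <- c("correct_name", "incorrect_name", "catch")
METACOG <- c("absent", "present")
CONFCAT <- c("conf_incorrect", "not_conf", "conf_correct")

## Canonical 6-cell order: metacog slow, confcat fast.
CELLS <- as.vector(outer(CONFCAT, METACOG, function(cc, m) paste(m, cc, sep = ".")))

#' Derive a reproducible stream of child seeds from one master seed
#'
#' All randomness in the package flows from integer seeds. Where a procedure
#' needs several independent random stages (restarts, bootstrap replicates,
#' per-participant simulation), it draws one child seed per stage from this
#' stream, so stage `i` gets the same seed regardless of how many stages run
#' or in which order.
#'
#' @param seed Master seed (a single integer).
#' @param n Number of child seeds to draw.
#' @return An integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @examples
#' seed_stream(42, 3)
#' @export
seed_stream <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(n), n >= 0)
  if (n == 0) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

## run `expr` with a local RNG state seeded by `seed`; restores caller's state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## numeric scalar check helper for argument validation
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict = c(FALSE, FALSE)) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  lo_ok <- if (strict[1]) x > lower else x >= lower
  hi_ok <- if (strict[2]) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    abort(sprintf("`%s` = %g is outside its allowed range %s%g, %g%s.",
                  name, x, if (strict[1]) "(" else "[", lower, upper,
                  if (strict[2]) ")" else "]"))
  invisible(x)
}
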