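#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois rexp rcauchy rt quantile sd
#'   shapiro.test hclust as.dist setNames dnorm dt dcauchy dexp median
#'   acf var
#' @importFrom utils read.table write.table head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  All generators route randomness through
# this so no function touches global random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad_arg <- function(...) stop(..., call. = FALSE)
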