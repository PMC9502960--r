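#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm median pnorm psignrank pt qnorm quantile rnorm
#'   runif sd setNames var
#' @importFrom utils read.csv unzip write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed error helper: every package error carries "octaconcord_error" plus a
# specific class so callers/tests can discriminate failure modes.
oc_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "octaconcord_error")))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulation functions are deterministic
#' in their `seed` argument without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stream offset, kept within the
# 32-bit signed integer range.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587L) + 1L
}
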