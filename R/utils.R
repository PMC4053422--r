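#' @importFrom rlang .data %||%
#' @importFrom stats plogis qlogis quantile rnorm rbinom rpois runif sd var
#'   lm coef dbinom predict uniroot
#' @importFrom utils head tail
#' @useDynLib apcforecast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Cohort index matrix over an I x J grid for band-width C.
cohort_grid <- function(I, J, C) {
  outer(seq_len(I), seq_len(J), function(i, j) cohort_index(i, j, I = I, C = C))
}
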