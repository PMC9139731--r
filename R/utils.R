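#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd lm t.test pt coef setNames
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib pkdseg, .registration = TRUE
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 9973) %% 2147483563L) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
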