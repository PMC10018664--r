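#' @useDynLib respredict, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile runif rnorm sd var pf median predict
#' @importFrom utils read.csv write.csv head tail
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards,
# so seeded operations behave as pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  if (nonneg && x < 0) stopf("`%s` must be >= 0", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
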