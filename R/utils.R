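#' @importFrom methods new validObject is slot
#' @importFrom stats median qbeta pchisq pt pnorm cor cor.test quantile
#'   rnorm rbinom runif rlnorm sd setNames chisq.test t.test wilcox.test
#'   hclust dist cutree predict
#' @importFrom utils read.csv write.csv read.delim head
NULL

## Structured conditions: input errors cover malformed arguments, degenerate
## errors cover data that make a stage mathematically undefined.
inputError <- function(msg, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c("rppasig_input_error", "error"),
                      call = call.))
}

degenerateError <- function(msg, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c("rppasig_degenerate_error", "error"),
                      call = call.))
}

## round() uses banker's rounding; report tables want conventional half-up.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## All generator randomness is routed through an explicit seed so identical
## specs are bit-identical, without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    inputError("'seed' must be a single integer")
  withr::with_seed(as.integer(seed), code)
}

checkScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    inputError(sprintf("'%s' must be a single non-missing number", name))
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    inputError(sprintf("'%s' = %g is outside its valid range", name, x))
  invisible(x)
}

centerRowMedians <- function(m) {
  m - apply(m, 1L, median)
}
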