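#' @keywords internal
"_PACKAGE"

#' @useDynLib multigrn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif var coef predict
#' @importFrom utils read.delim write.table combn
NULL

## z-score with population (1/n) denominator so a standardized vector of
## length n has sum of squares exactly n; zero-variance vectors map to zeros.
standardize_vector <- function(x) {
  n <- length(x)
  mu <- mean(x)
  s <- sqrt(sum((x - mu)^2) / n)
  if (s == 0) return(rep(0, n))
  (x - mu) / s
}

## standardize each row of a matrix (rows are variables, columns observations)
standardize_rows <- function(m) {
  out <- t(apply(m, 1, standardize_vector))
  dimnames(out) <- dimnames(m)
  out
}

soft_threshold <- function(x, lambda) {
  sign(x) * pmax(abs(x) - lambda, 0)
}

## fractional ranks, largest value first, ties averaged
rank_desc <- function(x) rank(-x, ties.method = "average")

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic integer sub-seed for a named random substream; keeps the
## derived seed inside 32-bit integer range
substream_seed <- function(seed, stream, index = 0L) {
  offsets <- c(truth = 11L, activities = 23L, noise = 37L, prior = 53L,
               splits = 71L, bootstrap = 97L)
  if (!stream %in% names(offsets)) stop_msg("unknown random substream '%s'", stream)
  base <- (as.numeric(seed) + offsets[[stream]] * 1e4 + as.numeric(index)) %%
    .Machine$integer.max
  as.integer(base)
}
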