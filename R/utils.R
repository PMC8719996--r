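#' @useDynLib obstruseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var cov quantile setNames
#' @importFrom utils write.csv head tail
NULL

# Internal validation helper: stop with a classed condition so callers/tests
# can distinguish user errors from bugs.
abort_validation <- function(msg) {
  stop(structure(class = c("obstruseg_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check <- function(ok, msg) {
  if (!isTRUE(ok)) abort_validation(msg)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations are pure
#' functions of their inputs and never disturb the caller's RNG stream.
#' With `seed = NULL` the expression draws from the current stream.
#'
#' @param seed integer seed or `NULL`
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check(is_count(seed, min = 0L), "seed must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derivation of sub-seeds from a master seed, kept < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629)
}

# ISO-timestamped log line carrying the active seed, per the package's
# logging convention.  Quiet unless options(obstruseg.verbose = TRUE).
log_msg <- function(fmt, ..., seed = NA) {
  if (!isTRUE(getOption("obstruseg.verbose", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] [seed=%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  as.character(seed), sprintf(fmt, ...)))
}
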