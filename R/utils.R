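#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov bartlett.test coef complete.cases dnorm kruskal.test
#'   lm logLik median pnorm predict quantile rbinom rnorm runif sd setNames
#'   shapiro.test TukeyHSD AIC as.formula binomial cor deviance p.adjust
#'   rexp rpois vcov
#' @importFrom utils combn head read.csv tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package funnel their `seed` argument
#' through this helper so that the caller's RNG state is never disturbed.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

## simple per-session message log for dropped-record accounting
.ss_log_env <- new.env(parent = emptyenv())

ss_log <- function(stage, msg) {
  entry <- sprintf("[%s] %s", stage, msg)
  .ss_log_env$log <- c(.ss_log_env$log %||% character(), entry)
  invisible(entry)
}

#' Retrieve (and optionally clear) the package's dropped-record log
#'
#' Several operations drop records (dives without bracketing fixes, points
#' outside the raster extent, single-fix trips). Each drop is counted here.
#'
#' @param clear logical; clear the log after reading.
#' @return character vector of log entries.
#' @export
ss_get_log <- function(clear = FALSE) {
  out <- .ss_log_env$log %||% character()
  if (clear) .ss_log_env$log <- character()
  out
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar", name), call. = FALSE)
  invisible(x)
}
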