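#' @keywords internal
"_PACKAGE"

#' @useDynLib canopystack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate coef complete.cases cor dist dnorm lm median
#'   optim pnorm qnorm quantile rnorm runif sd setNames var approx
#' @importFrom utils head read.csv tail write.csv
NULL

# Deterministic per-stage seed fan-out: one user seed expands to independent
# stage seeds without exceeding .Machine$integer.max (R seeds are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offs <- c(qc = 1L, field = 2L, footprints = 3L, plots = 4L, variogram = 5L,
            interpolate = 6L, select = 7L, stack = 8L, map = 9L, split = 10L,
            bench = 11L)
  k <- if (is.character(stage)) {
    if (!stage %in% names(offs)) abs(sum(utf8ToInt(stage))) %% 1000L else offs[[stage]]
  } else as.integer(stage)
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_schema <- function(...) stop(sprintf(...), call. = FALSE)
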