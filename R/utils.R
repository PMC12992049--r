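#' @useDynLib cvbflmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom quantile sd uniroot setNames
#' @importFrom utils read.csv write.csv
NULL

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named substreams, so that each stage (simulation, splitting, sampling,
#' bootstrap) is independently reproducible.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @param index integer index within the stage (e.g. split number).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  h <- abs(as.numeric(master)) %% m
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  h <- (h * 31 + abs(as.numeric(index))) %% m
  as.integer(h %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
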