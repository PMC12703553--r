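#' @import methods
#' @importFrom stats cor sd quantile rnorm runif rbinom qnorm pnorm pt qt
#'   t.test p.adjust lm.fit setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

#' Package logging
#'
#' One timestamped line per operation. Logging is silent unless the option
#' \code{dualconn.verbose} is \code{TRUE}; messages go through
#' \code{message()} so they can be captured or suppressed as usual.
#'
#' @param fmt \code{sprintf}-style format string.
#' @param ... values interpolated into \code{fmt}.
#' @return invisibly, the formatted line.
#' @export
fcLog <- function(fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  if (isTRUE(getOption("dualconn.verbose", FALSE))) message(line)
  invisible(line)
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' A single global seed plus a stage name deterministically yields a
#' per-stage seed, so individual stages can be re-run in isolation without
#' replaying the whole pipeline's random stream.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return a single integer in \code{[0, 2^31 - 2]}.
#' @export
childSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

# i<j pairs of the upper triangle in fixed lexicographic (i, then j) order
upperPairs <- function(R) {
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(k) (k + 1L):R), use.names = FALSE)
  cbind(i = i, j = j)
}

# local RNG scope: run expr under set.seed(seed) and restore the caller's stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
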