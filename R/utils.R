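#' @useDynLib anchorProg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor median pchisq quantile rexp rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

## Stage logging: stderr message with a uniform prefix so pipeline runs are
## greppable; optionally mirrored to a run-log file set by runPipeline().
.logEnv <- new.env(parent = emptyenv())

apLog <- function(...) {
  txt <- paste0("[anchorProg] ", ...)
  message(txt)
  lf <- .logEnv$logFile
  if (!is.null(lf)) cat(txt, "\n", file = lf, append = TRUE, sep = "")
  invisible(txt)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Stages of the pipeline draw their own seeds deterministically from one
#' master seed and the stage name, so any stage can be re-run in isolation
#' with identical results.  The derivation is a small polynomial string hash
#' folded into the 32-bit signed integer range.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stageSeed(1, "train")
stageSeed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(as.numeric(master)) * 2654435 + h) %% 2147483646)
}

## internal: stop unless all named checks are TRUE
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
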