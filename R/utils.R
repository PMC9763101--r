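#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd median qnorm pnorm qbeta pbeta rnorm rbinom rnbinom
#'   runif lm lm.fit lm.wfit coef optim optimize smooth.spline predict pt qt
#'   var fisher.test wilcox.test complete.cases prcomp rbeta quantile ks.test
#'   setNames p.adjust dnbinom rmultinom dbeta
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lightweight logging: messages are emitted unless options(crdscan.quiet=TRUE).
crd_log <- function(fmt, ...) {
  if (isTRUE(getOption("crdscan.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(fmt, ...))
}

crd_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a child seed from a base seed and a stage name
#'
#' Stage-level seeds are derived deterministically so that individual pipeline
#' stages are reproducible in isolation without seed collisions between stages.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed Base integer seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Format numeric columns at 6 significant digits for TSV output.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}
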