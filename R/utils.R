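#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rpois rbinom rgamma rnorm runif median quantile
#'   optimize pf var t.test phyper p.adjust setNames aggregate sd cor
#' @importFrom utils write.table read.delim head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ilseq <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_ilseq(msg)
  invisible(TRUE)
}

BASES <- c("A", "C", "G", "T")

## Deterministic child seed for a pipeline stage; keeps values < 2^31.
stage_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
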