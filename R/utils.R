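# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Fixed multiplicative splitting keyed by a stream index, so that adding
#' later streams (species, replicates, sites) never perturbs earlier draws.
#' Result stays within the 32-bit signed integer range R requires.
#'
#' @param master integer master seed
#' @param index non-negative integer stream index
#' @param stream small integer distinguishing independent purposes
#' @return an integer seed
#' @keywords internal
split_seed <- function(master, index, stream = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483629 # largest prime < 2^31
  s <- (as.double(master) %% m)
  s <- (s * 48271 + as.double(index) * 16807 + as.double(stream) * 69621) %% m
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_reach <- function(msg, reach) {
  stop(sprintf("%s (reach '%s')", msg, reach), call. = FALSE)
}
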