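#' Derive an independent child seed from a master seed
#'
#' A single run seed drives several independent random streams (landscape,
#' demography, genotyping error, permutations). Child seeds are derived by a
#' 32-bit integer hash of the master seed and a stream label so that streams
#' are reproducible and decoupled: changing how many draws one stream consumes
#' never perturbs another.
#'
#' @param seed master seed (single integer).
#' @param stream character label of the stream.
#' @return a single integer in `[0, 2^31 - 1]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  # one multiplicative scramble to decorrelate consecutive seeds
  as.integer((h * 48271) %% 2147483647)
}

#' Log a pipeline stage to stderr with elapsed time
#'
#' @param msg message to log.
#' @param t0 optional `proc.time()` snapshot; when given, elapsed seconds are
#'   appended.
#' @return invisibly, the current `proc.time()`.
#' @export
log_stage <- function(msg, t0 = NULL) {
  if (!is.null(t0)) {
    dt <- (proc.time() - t0)[["elapsed"]]
    msg <- sprintf("%s [%.2fs]", msg, dt)
  }
  message(sprintf("[costsweep %s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  invisible(proc.time())
}

# internal: stop unless all conditions hold, with a formatted message
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
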