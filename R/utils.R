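#' @keywords internal
"_PACKAGE"

#' @useDynLib bionertl, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif sd setNames
#' @importFrom utils head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Package-level logging: terse messages to stderr, silenced unless
# options(bionertl.verbose = TRUE).
log_msg <- function(...) {
  if (isTRUE(getOption("bionertl.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

# Derive a child seed from a base seed; kept well below 2^31.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 7919 + as.double(o) + 1) %% 2147480000
  as.integer(s)
}

is_probability <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
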