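# Internal helpers: classed conditions, log-space sums, seed stream mixing.

glyrare_stop <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "glyrare_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

glyrare_warn <- function(class, msg) {
  cond <- structure(
    class = c(class, "glyrare_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cond)
}

# sum(exp(x)) in log space without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a child seed from a master seed and a stream index
#'
#' All randomness in the package flows from one integer seed; independent
#' streams (cohorts, replicates) mix their index into the master seed so that
#' streams are reproducible individually and jointly. Results stay within
#' 32-bit integer range.
#'
#' @param seed master integer seed
#' @param index non-negative stream index
#' @return an integer seed
#' @export
mix_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 16807 + 11
  as.integer(s %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
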