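# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used wherever percentages are reported to a
#' fixed number of decimals. Base `round()` rounds half to even, which would
#' turn e.g. 97.885 into 97.88 rather than 97.89.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Classed conditions: identity errors (duplicate/unknown identifiers), coding
# errors (unresolvable genotype tokens) and configuration errors are
# distinguishable by class so callers and the pipeline can map them to exit
# causes.
stop_identity <- function(...) stop_minmark(sprintf(...), "minmark_identity_error")
stop_coding   <- function(...) stop_minmark(sprintf(...), "minmark_coding_error")
stop_config   <- function(...) stop_minmark(sprintf(...), "minmark_config_error")

stop_minmark <- function(msg, class) {
  stop(structure(
    class = c(class, "minmark_error", "error", "condition"),
    list(message = msg, call = sys.call(-2))
  ))
}

# Upper-triangle pair indices for n items, in lexicographic (i < j) order.
pair_indices <- function(n) {
  if (n < 2L) {
    return(list(i = integer(0), j = integer(0)))
  }
  j <- rep(2:n, 1:(n - 1L))
  i <- sequence(1:(n - 1L))
  list(i = i, j = j)
}
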