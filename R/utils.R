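# Physical constants (CODATA)
.FARADAY <- 96485.332   # C/mol
.GAS_R <- 8.314462618   # J/(mol K)

#' Cumulative trapezoidal integral
#'
#' @param x ordinate vector (strictly increasing)
#' @param y values at `x`
#' @return vector of the same length; first element 0
#' @keywords internal
cumtrapz_ <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("cumulative integral needs at least 2 samples")
  c(0, cumsum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Deterministic stage-local seed: base seed plus a small hash of the stage
# name, kept inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100000L
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}
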