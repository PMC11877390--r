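#' @useDynLib speckledrink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median quantile runif rnorm sd var kruskal.test
#'   wilcox.test p.adjust predict
#' @importFrom utils read.csv write.csv head
NULL

# Lehmer-step seed derivation: one master seed fans out to per-stage /
# per-item seeds without collisions. 48271 * 2^31 < 2^53 so the arithmetic
# is exact in doubles; results stay in [1, 2^31 - 2].
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647
  s <- (abs(master) %% m) + 1
  for (k in counter) {
    s <- (48271 * s + (abs(k) %% m)) %% m
    if (s == 0) s <- 1
  }
  as.integer(s)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_invalid("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_invalid("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_invalid("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

#' Five measurement time-point labels
#'
#' The fixed vocabulary of recording time points: before drinking, right
#' after drinking, and 30/60/90 minutes after.
#'
#' @return Character vector of the five labels, in chronological order.
#' @export
time_labels <- function() {
  c("before drinking", "0 min", "30 min", "60 min", "90 min")
}
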