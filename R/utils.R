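# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's RNG stream. Used by every stochastic operation that accepts a
#' `seed` argument.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed; kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

#' Unwrap a phase sequence
#'
#' Removes 2*pi discontinuities so that no successive difference exceeds pi in
#' magnitude, matching the usual `unwrap` of signal-processing toolboxes.
#'
#' @param p numeric vector of phase angles (rad).
#' @return numeric vector of unwrapped phases.
#' @export
unwrap_phase <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) < 2L) return(p)
  dp <- diff(p)
  jump <- round(dp / (2 * pi))
  p - c(0, cumsum(jump)) * 2 * pi
}

# Discrete-time Fourier transform of x at normalized frequencies f
# (cycles/sample): X(f) = sum_n x[n] exp(-j 2 pi f n), n = 0..N-1.
dtft <- function(x, f) {
  n <- seq_along(x) - 1
  vapply(f, function(ff) sum(x * exp(-2i * pi * ff * n)), complex(1))
}

db <- function(x) 10 * log10(x)
undb <- function(x) 10^(x / 10)

# Power of a (possibly complex) series.
sig_power <- function(x) mean(Mod(x)^2)

# Largest-magnitude local maxima of a numeric vector; returns indices sorted
# by decreasing value. Interior maxima only (strictly greater than one
# neighbour, not less than the other).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  idx <- i[v[i] >= v[i - 1] & v[i] > v[i + 1]]
  idx[order(v[idx], decreasing = TRUE)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
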