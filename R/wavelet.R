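# Orthogonal discrete wavelet transform (Daubechies db4, periodized) and
# universal-threshold denoising.

# db4 (8-tap Daubechies) scaling filter; sums to sqrt(2).
DB4_LO <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1, 1, -1, 1, -1)

dwt_step <- function(x, h, g) {
  n <- length(x)
  k <- seq(0, n - 2, by = 2)
  idx <- outer(k, seq_along(h) - 1, "+") %% n + 1   # (n/2) x L sample index
  list(a = as.numeric(matrix(x[idx], ncol = length(h)) %*% h),
       d = as.numeric(matrix(x[idx], ncol = length(g)) %*% g))
}

idwt_step <- function(a, d, h, g) {
  n <- 2 * length(a)
  x <- numeric(n)
  for (j in seq_along(h)) {
    pos <- (2 * (seq_along(a) - 1) + (j - 1)) %% n + 1
    contrib <- a * h[j] + d * g[j]
    # accumulate; positions can repeat when n < filter support
    for (q in seq_along(pos)) x[pos[q]] <- x[pos[q]] + contrib[q]
  }
  x
}

# Periodized multilevel db4 DWT; returns list(approx, details = list by level).
dwt_db4 <- function(x, levels) {
  a <- x
  details <- vector("list", levels)
  for (lv in seq_len(levels)) {
    st <- dwt_step(a, DB4_LO, DB4_HI)
    a <- st$a
    details[[lv]] <- st$d
  }
  list(approx = a, details = details)
}

idwt_db4 <- function(w) {
  a <- w$approx
  for (lv in rev(seq_along(w$details)))
    a <- idwt_step(a, w$details[[lv]], DB4_LO, DB4_HI)
  a
}

#' Wavelet-threshold denoising
#'
#' Multi-level periodized db4 decomposition with soft universal thresholding
#' of detail coefficients. The input is symmetrically extended (so the
#' periodic transform sees no boundary jump), the noise scale is estimated
#' from the median absolute deviation of the finest-level details
#' (`sigma = median(|d1|) / 0.6745`) and the finest `threshold_levels` detail
#' levels are soft-shrunk by `sigma * sqrt(2 log n)` before reconstruction.
#' Oscillatory physiological components are not sparse in db4, so only the
#' detail levels above the signal band are shrunk (at the 20 Hz design rate,
#' levels 1-2 cover 2.5-10 Hz, above the heartbeat band); coarser levels and
#' the approximation pass through untouched. Length is preserved.
#'
#' @param x real series; length must be at least `2^levels`.
#' @param levels decomposition depth (default 4).
#' @param threshold_levels how many of the finest detail levels to shrink
#'   (default 2).
#' @return denoised series of the same length.
#' @export
wavelet_denoise <- function(x, levels = 4L, threshold_levels = 2L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2^levels) stop("series shorter than 2^levels")
  # symmetric extension, padded periodically to a multiple of 2^levels:
  # continuous across the wrap, so no boundary artifacts pollute d1
  block <- 2^levels
  m <- as.integer(ceiling(2 * n / block) * block)
  xp <- rep_len(c(x, rev(x)), m)
  w <- dwt_db4(xp, levels)
  sigma <- stats::median(abs(w$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(xp)))
  shrink <- seq_len(min(threshold_levels, levels))
  w$details[shrink] <- lapply(w$details[shrink],
                              function(d) sign(d) * pmax(abs(d) - thr, 0))
  y <- idwt_db4(w)
  y[seq_len(n)]
}
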