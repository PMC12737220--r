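# Local mean decomposition: sifting a series into product functions
# (envelope x frequency-modulated carrier).

# Indices of local extrema (maxima and minima), endpoints included.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(c(1L, n))
  d <- diff(x)
  s <- sign(d)
  # treat flats as continuing the previous slope
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) != 0) + 1L
  unique(c(1L, idx, n))
}

# Moving-average smoothing with edge padding; window forced odd.
smooth_ma <- function(x, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  half <- w %/% 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(half + 1):(half + length(x))]
}

# One sifting pass: piecewise local mean and magnitude from successive
# extrema, smoothed by a moving average spanning the widest extrema gap.
local_mean_env <- function(x) {
  ext <- find_extrema(x)
  if (length(ext) < 3) return(NULL)
  m_step <- numeric(length(x))
  a_step <- numeric(length(x))
  for (i in seq_len(length(ext) - 1)) {
    seg <- ext[i]:ext[i + 1]
    m_step[seg] <- (x[ext[i]] + x[ext[i + 1]]) / 2
    a_step[seg] <- abs(x[ext[i]] - x[ext[i + 1]]) / 2
  }
  w <- max(diff(ext))
  list(m = smooth_ma(m_step, w), a = pmax(smooth_ma(a_step, w), 1e-12),
       n_extrema = length(ext))
}

#' Local mean decomposition into product functions
#'
#' Decomposes a series into product functions (PFs), each the product of an
#' instantaneous envelope and a purely frequency-modulated carrier, by
#' iterative sifting: the smoothed local mean is subtracted and the result
#' demodulated by the smoothed local magnitude until the carrier envelope is
#' close to unity. The final residual is whatever remains after the last PF,
#' so `rowSums(pfs) + residual` reconstructs the input exactly.
#'
#' @param x real, non-constant series.
#' @param max_pf maximum number of product functions to extract.
#' @param max_sift sifting iterations per PF.
#' @param envelope_tol unit-envelope tolerance for sifting convergence.
#' @param stop_energy stop extracting once the residual holds less than this
#'   fraction of the input energy (a mono-component input then yields a
#'   single PF).
#' @param rate sampling rate, Hz (for the reported center frequencies).
#' @return a `mode_set` with `source = "lmd"`; extra element `residual_series`
#'   holds the unexplained remainder. If no PF is extractable the input is
#'   returned as a single flagged PF.
#' @export
lmd_decompose <- function(x, max_pf = 8L, max_sift = 12L,
                          envelope_tol = 0.02, stop_energy = 0.01,
                          rate = 20) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) stop("lmd_decompose needs a non-constant input")
  residual <- x
  pfs <- list()
  for (np in seq_len(max_pf)) {
    if (sum(residual^2) < stop_energy * sum(x^2)) break
    if (length(find_extrema(residual)) < 5) break
    s <- residual
    a_total <- rep(1, length(x))
    ok <- FALSE
    for (it in seq_len(max_sift)) {
      me <- local_mean_env(s)
      if (is.null(me)) break
      h <- s - me$m
      s <- h / me$a
      a_total <- a_total * me$a
      # converged when the residual envelope is ~1
      me2 <- local_mean_env(s)
      if (is.null(me2)) break
      if (max(abs(me2$a - 1)) < envelope_tol) { ok <- TRUE; break }
      ok <- TRUE   # partial sifting still yields a usable PF
    }
    if (!ok) break
    pf <- a_total * s
    if (sum(pf^2) < 1e-12 * sum(x^2)) break
    pfs[[np]] <- pf
    residual <- residual - pf
  }
  flags <- character(0)
  if (length(pfs) == 0) {
    pfs <- list(x)
    residual <- rep(0, length(x))
    flags <- "lmd_no_pf_extracted"
  }
  modes <- do.call(cbind, pfs)
  cf <- vapply(seq_len(ncol(modes)), function(k) {
    dominant_frequency(modes[, k], rate)
  }, numeric(1))
  out <- new_mode_set(modes, cf, rate, "lmd",
                      residual = sqrt(sum(residual^2) / sum(x^2)),
                      converged = TRUE, flags = flags)
  out$residual_series <- residual
  out
}

# Frequency of the largest positive-frequency spectral line.
dominant_frequency <- function(x, rate) {
  n <- length(x)
  X <- Mod(stats::fft(x - mean(x)))
  half <- 2:(n %/% 2)
  (which.max(X[half])) / n * rate
}

#' Correlation gating of product functions
#'
#' Keeps the PF components whose Pearson correlation with the reference
#' vital-sign signal strictly exceeds the threshold `rho`; the rest are
#' discarded as interference or noise. Zero-variance components are given
#' r = 0.
#'
#' @param pfs numeric matrix with one PF per column (or a `mode_set`).
#' @param reference the original vital-sign series (same length).
#' @param rho correlation threshold (default 0.35; comparison is strict).
#' @return matrix of kept PFs (possibly zero columns) with attributes
#'   `correlations` (all PFs) and `kept` (indices).
#' @export
correlation_select <- function(pfs, reference, rho = 0.35) {
  if (inherits(pfs, "mode_set")) pfs <- pfs$modes
  pfs <- as.matrix(pfs)
  stopifnot(nrow(pfs) == length(reference))
  r <- vapply(seq_len(ncol(pfs)), function(k) {
    if (stats::sd(pfs[, k]) == 0 || stats::sd(reference) == 0) return(0)
    stats::cor(pfs[, k], reference)
  }, numeric(1))
  kept <- which(r > rho)
  structure(pfs[, kept, drop = FALSE], correlations = r, kept = kept)
}
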