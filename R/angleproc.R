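# Angle-domain processing: Doppler accumulation, Root-MUSIC DOA estimation
# and MVDR beamforming separation of co-range targets.

# Steering vector of an I-element uniform linear array toward theta (deg).
steering_vector <- function(theta_deg, I, d_over_lambda = 0.5) {
  exp(2i * pi * d_over_lambda * (0:(I - 1)) * sinpi(theta_deg / 180))
}

#' Doppler-domain snapshot accumulation
#'
#' Runs a Doppler FFT along slow time in every channel of an N x I range-bin
#' slice and retains the Doppler bins with the highest channel-summed power
#' as high-SNR spatial snapshots. The FFT is linear per channel, so the
#' inter-channel phase structure (hence the DOA information) is preserved
#' while the target's energy is compressed into few bins.
#'
#' @param slice complex N x I matrix: slow-time samples of one range bin
#'   across the virtual channels.
#' @param n_snapshots number of Doppler bins to retain (default 8).
#' @return complex `n_snapshots` x I snapshot matrix with attribute
#'   `doppler_bins` (0-based retained bin indices).
#' @export
doppler_accumulate <- function(slice, n_snapshots = 8L) {
  slice <- as.matrix(slice)
  if (all(Mod(slice) == 0)) stop("all-zero slice")
  D <- stats::mvfft(slice)                  # N x I, Doppler x channel
  pw <- rowSums(Mod(D)^2)
  keep <- order(pw, decreasing = TRUE)[seq_len(min(n_snapshots, nrow(D)))]
  structure(D[keep, , drop = FALSE], doppler_bins = keep - 1L)
}

# Sample spatial covariance R = mean_n x_n x_n^H of snapshot rows x_n^T,
# with diagonal loading.
snapshot_covariance <- function(snapshots, loading = 1e-3) {
  X <- as.matrix(snapshots)
  R <- crossprod(X, Conj(X)) / nrow(X)      # R[i,j] = mean x_i conj(x_j)
  R + diag(loading * Re(sum(diag(R))) / ncol(X), ncol(X))
}

#' Estimate the number of sources by the eigenvalue gap
#'
#' Returns the index of the largest ratio between consecutive sorted
#' eigenvalues of the spatial covariance, capped at `max_sources`.
#'
#' @param R complex spatial covariance (I x I).
#' @param max_sources upper bound on the estimate (default I - 2).
#' @return integer source-count estimate.
#' @export
estimate_n_sources <- function(R, max_sources = ncol(R) - 2L) {
  ev <- sort(Re(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  ev <- pmax(ev, .Machine$double.eps)
  ratios <- ev[-length(ev)] / ev[-1]
  as.integer(min(which.max(ratios[seq_len(max_sources)]), max_sources))
}

#' Root-MUSIC direction-of-arrival estimation
#'
#' Subspace DOA estimation on snapshot rows from a uniform linear array:
#' eigendecompose the sample covariance, form the noise-subspace polynomial
#' `p(z) = a(1/z*)^H En En^H a(z)`, root it, keep the `n_sources` roots
#' inside and nearest the unit circle, and map each root phase to
#' `theta = asin(arg(z) / (2 pi d/lambda))`.
#'
#' @param snapshots complex n x I snapshot matrix (rows are snapshots), or a
#'   precomputed I x I covariance with `is_covariance = TRUE`.
#' @param n_sources number of sources to estimate (< I).
#' @param d_over_lambda element spacing over wavelength (default 1/2).
#' @param is_covariance set to `TRUE` when `snapshots` is already a spatial
#'   covariance matrix.
#' @return object of class `doa_estimate`: list with `angles` (deg, sorted
#'   ascending), `roots`, `n_sources` and `degenerate` flag (covariance rank
#'   below the requested source count).
#' @export
root_music <- function(snapshots, n_sources = 1L, d_over_lambda = 0.5,
                       is_covariance = FALSE) {
  R <- if (is_covariance) as.matrix(snapshots) else snapshot_covariance(snapshots)
  I <- ncol(R)
  if (n_sources >= I) stop("n_sources must be smaller than the channel count")
  eg <- eigen(R)
  degenerate <- sum(Re(eg$values) > max(Re(eg$values)) * 1e-10) < n_sources
  En <- eg$vectors[, (n_sources + 1):I, drop = FALSE]
  C <- En %*% Conj(t(En))
  # a^H C a = sum_k (sum over k-th superdiagonal of C) z^k at z = e^{j phi},
  # so the coefficient of z^k sums entries with col - row = k; polyroot
  # wants ascending powers, k = -(I-1) .. (I-1).
  coefs <- vapply(-(I - 1):(I - 1), function(k) {
    idx <- which(col(C) - row(C) == k)
    sum(C[idx])
  }, complex(1))
  rts <- polyroot(coefs)
  inside <- rts[Mod(rts) <= 1]
  if (length(inside) < n_sources) inside <- rts     # degenerate fallback
  sel <- inside[order(abs(Mod(inside) - 1))][seq_len(n_sources)]
  sin_theta <- Arg(sel) / (2 * pi * d_over_lambda)
  sin_theta <- pmin(1, pmax(-1, sin_theta))
  angles <- sort(asin(sin_theta) * 180 / pi)
  structure(list(angles = angles, roots = sel, n_sources = n_sources,
                 degenerate = degenerate),
            class = "doa_estimate")
}

#' @export
print.doa_estimate <- function(x, ...) {
  cat(sprintf("Root-MUSIC DOA: %s deg%s\n",
              paste(sprintf("%+.2f", x$angles), collapse = ", "),
              if (x$degenerate) " [degenerate covariance]" else ""))
  invisible(x)
}

#' MVDR (Capon) beamforming separation
#'
#' Separates the signal arriving from `theta0` out of an N x I range-bin
#' slice with minimum-variance distortionless-response weights
#' `w = R^-1 a / (a^H R^-1 a)`, so that `w^H a(theta0) = 1` exactly while
#' total output power is minimized (interferers from other angles are
#' suppressed). The covariance is estimated from the slice itself (or
#' supplied), with diagonal loading for invertibility.
#'
#' @param slice complex N x I matrix (slow time x channel) at one range bin.
#' @param theta0 steering angle, deg.
#' @param d_over_lambda element spacing over wavelength.
#' @param R optional I x I covariance; default is the sample covariance of
#'   the slice rows.
#' @param loading diagonal loading as a fraction of `trace(R)/I`.
#' @return complex slow-time series of length N with attributes `weights`
#'   and `theta0`.
#' @export
mvdr_separate <- function(slice, theta0, d_over_lambda = 0.5, R = NULL,
                          loading = 1e-3) {
  slice <- as.matrix(slice)
  I <- ncol(slice)
  if (I == 1) return(structure(slice[, 1], weights = 1 + 0i, theta0 = theta0))
  if (is.null(R)) R <- snapshot_covariance(slice, loading)
  a <- steering_vector(theta0, I, d_over_lambda)
  Ria <- tryCatch(solve(R, a), error = function(e) {
    solve(R + diag(loading * Re(sum(diag(R))) / I, I), a)
  })
  w <- Ria / as.complex(Conj(a) %*% Ria)    # w^H a = 1 by construction
  y <- as.vector(slice %*% Conj(w))
  structure(y, weights = w, theta0 = theta0)
}
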