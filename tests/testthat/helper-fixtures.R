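# Shared fixtures and independent oracles for the test suite.

# Default 77 GHz configuration used throughout.
test_config <- function() radar_config()

# Two-subject occlusion scene: 0.8 m and 1.5 m on boresight.
occlusion_scene <- function(seed = 1L, snr_db = 20, duration = 40) {
  radar_scene(list(
    radar_target(0.8, 0, vital_profile(heartbeat_frequency = 1.233)),
    radar_target(1.5, 0, vital_profile(respiration_frequency = 0.25,
                                       heartbeat_frequency = 1.45,
                                       respiration_phase = 1.1))),
    snr_db = snr_db, duration = duration, seed = seed)
}

# Co-range scene: both subjects at 1.2 m, 25 deg apart.
corange_scene <- function(seed = 1L, snr_db = 20, duration = 40,
                          angles = c(0, 25)) {
  radar_scene(list(
    radar_target(1.2, angles[1], vital_profile(heartbeat_frequency = 1.1)),
    radar_target(1.2, angles[2], vital_profile(respiration_frequency = 0.33,
                                               heartbeat_frequency = 1.4,
                                               respiration_phase = 2.1))),
    snr_db = snr_db, duration = duration, seed = seed)
}

# Synthetic phase-domain vital fixture (radians at the slow-time rate):
# respiration + harmonics + heartbeat via the displacement model, plus
# white phase noise.
phase_fixture <- function(seed = 1L, n = 512, rate = 20, snr_db = 10,
                          heartbeat_frequency = 1.233) {
  v <- vital_profile(heartbeat_frequency = heartbeat_frequency)
  lam <- radar_config()$wavelength
  x <- 4 * pi * chest_displacement(v, (0:(n - 1)) / rate) / lam
  add_awgn(x, snr_db, seed = seed)
}

# Independent DBSCAN oracle built on igraph connected components:
# clusters = components of the eps-graph restricted to core points; border
# points join a neighboring core cluster; the rest is noise.
dbscan_oracle <- function(pts, eps, min_samples) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  D <- as.matrix(stats::dist(pts))
  core <- rowSums(D <= eps) >= min_samples
  labels <- integer(n)
  if (any(core)) {
    idx <- which(core)
    A <- (D[idx, idx, drop = FALSE] <= eps) * 1
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[idx] <- comp
    for (i in which(!core)) {
      nb <- idx[D[i, idx] <= eps]
      if (length(nb) > 0) labels[i] <- labels[nb[1]]
    }
  }
  labels
}

# Fine-grid spectral MUSIC DOA oracle (0.01 deg grid) from a covariance.
music_doa_oracle <- function(R, n_sources, d_over_lambda = 0.5,
                             grid = seq(-89.99, 89.99, by = 0.01)) {
  I <- ncol(R)
  eg <- eigen(R)
  En <- eg$vectors[, (n_sources + 1):I, drop = FALSE]
  A <- exp(2i * pi * d_over_lambda * outer(0:(I - 1), sinpi(grid / 180)))
  proj <- Conj(t(En)) %*% A
  pseudo <- 1 / colSums(Mod(proj)^2)
  pk <- integer(0)
  v <- pseudo
  for (k in seq_len(n_sources)) {
    i <- which.max(v)
    pk <- c(pk, i)
    v[max(1, i - 200):min(length(v), i + 200)] <- -Inf
  }
  sort(grid[pk])
}

# Deterministic multichannel slice for two far-field sources with given
# angles and per-snapshot complex amplitudes.
two_source_slice <- function(amp1, amp2, th1, th2, I = 8) {
  a <- function(th) exp(2i * pi * 0.5 * (0:(I - 1)) * sinpi(th / 180))
  outer(amp1, a(th1)) + outer(amp2, a(th2))
}
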