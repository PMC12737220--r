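# Angle processing: Doppler accumulation, Root-MUSIC, MVDR separation.

test_that("Doppler accumulation concentrates a moving phantom in one bin", {
  I <- 8
  n <- 128
  # constant-velocity phantom: Doppler frequency 0.25 cycles/sample -> bin 32
  amp <- exp(2i * pi * 0.25 * (0:(n - 1)))
  slice <- two_source_slice(amp, rep(0, n), 10, 0, I)
  snaps <- doppler_accumulate(slice, n_snapshots = 4)
  expect_equal(attr(snaps, "doppler_bins")[1], 32L)
  # retained power dominated by that bin
  pw <- rowSums(Mod(snaps)^2)
  expect_gt(pw[1] / sum(pw), 0.95)

  # white-noise input: retained power equals the top order statistics
  set.seed(5)
  noise <- matrix(complex(real = rnorm(n * I), imaginary = rnorm(n * I)),
                  n, I)
  sn <- doppler_accumulate(noise, n_snapshots = 8)
  D <- mvfft(noise)
  top <- sort(rowSums(Mod(D)^2), decreasing = TRUE)[1:8]
  expect_equal(sort(rowSums(Mod(sn)^2), decreasing = TRUE), top)

  expect_error(doppler_accumulate(matrix(0 + 0i, 16, 4)), "zero")
})

test_that("vital-sign slices concentrate energy at low Doppler bins", {
  cfg <- test_config()
  sc <- radar_scene(list(radar_target(0.9, 0, vital_profile())),
                    snr_db = Inf, duration = 6.4, seed = 1)
  rmap <- remove_clutter(range_fft(simulate_cube(sc, cfg)))
  snaps <- doppler_accumulate(rmap[22, , ])
  bins <- attr(snaps, "doppler_bins")
  n <- dim(rmap)[2]
  # map to signed Doppler bins; vital motion (respiration sidebands of a
  # ~13 rad modulation index reach a few Hz) stays in the lower quarter
  signed <- ifelse(bins > n / 2, bins - n, bins)
  expect_true(all(abs(signed) <= n / 4))
})

test_that("Root-MUSIC matches the fine-grid MUSIC oracle", {
  I <- 8
  n <- 64
  set.seed(6)
  # noiseless single source at 20 deg
  amp <- complex(real = rnorm(n), imaginary = rnorm(n))
  slice <- two_source_slice(amp, rep(0, n), 20, 0, I)
  est <- root_music(slice, 1)
  expect_equal(est$angles, 20, tolerance = 0.01)
  R <- radarhr:::snapshot_covariance(slice)
  oracle <- music_doa_oracle(R, 1)
  expect_equal(est$angles, oracle, tolerance = 0.1)

  # two noiseless sources at +-30 deg
  a2 <- complex(real = rnorm(n), imaginary = rnorm(n))
  slice2 <- two_source_slice(amp, a2, -30, 30, I)
  est2 <- root_music(slice2, 2)
  expect_equal(est2$angles, c(-30, 30), tolerance = 0.1)
  oracle2 <- music_doa_oracle(radarhr:::snapshot_covariance(slice2), 2)
  expect_equal(est2$angles, oracle2, tolerance = 0.1)
})

test_that("noise-polynomial roots occur in conjugate-reciprocal pairs", {
  I <- 6
  n <- 40
  set.seed(7)
  amp <- complex(real = rnorm(n), imaginary = rnorm(n))
  slice <- two_source_slice(amp, 0.5 * amp, -15, 40, I)
  slice <- slice + 0.05 * matrix(complex(real = rnorm(n * I),
                                         imaginary = rnorm(n * I)), n, I)
  R <- radarhr:::snapshot_covariance(slice)
  eg <- eigen(R)
  En <- eg$vectors[, 3:I]
  C <- En %*% Conj(t(En))
  coefs <- vapply(-(I - 1):(I - 1), function(k)
    sum(C[col(C) - row(C) == k]), complex(1))
  rts <- polyroot(coefs)
  # every root's conjugate reciprocal is also a root
  for (z in rts) {
    zr <- 1 / Conj(z)
    expect_lt(min(Mod(rts - zr)), 1e-6 * max(1, Mod(zr)))
  }
})

test_that("Root-MUSIC on synthetic cubes meets the 25-deg-separation envelope", {
  cfg <- test_config()
  devs <- c()
  for (seed in 1:3) {
    sc <- corange_scene(seed = seed, snr_db = 15, duration = 12.8)
    cube <- simulate_cube(sc, cfg)
    rmap <- remove_clutter(range_fft(cube))
    bin <- round(1.2 / cfg$range_bin_width)
    snaps <- doppler_accumulate(rmap[bin + 1L, 1:128, ])
    est <- root_music(snaps, 2)
    devs <- c(devs, abs(sort(est$angles) - c(0, 25)))
  }
  expect_lt(mean(devs), 2)
})

test_that("MVDR is distortionless and suppresses the interferer", {
  I <- 8
  a <- function(th) exp(2i * pi * 0.5 * (0:(I - 1)) * sinpi(th / 180))
  # known covariance: two equal-power sources + small noise floor
  R <- outer(a(-30), Conj(a(-30))) + outer(a(30), Conj(a(30))) + diag(1e-4, I)
  x <- matrix(a(-30) + a(30), nrow = 1)       # any snapshot row
  y <- mvdr_separate(x, theta0 = -30, R = R)
  w <- attr(y, "weights")
  expect_equal(as.complex(sum(Conj(w) * a(-30))), 1 + 0i, tolerance = 1e-10)
  # closed-form interferer gain >= 20 dB down
  supp <- 20 * log10(Mod(sum(Conj(w) * a(30))))
  expect_lt(supp, -20)

  # single-channel degenerate array: passthrough up to scale
  z <- complex(real = rnorm(16), imaginary = rnorm(16))
  y1 <- mvdr_separate(matrix(z, ncol = 1), 0)
  expect_equal(as.complex(y1), z)
})

test_that("MVDR-separated co-range targets carry their own heartbeat", {
  cfg <- test_config()
  # heartbeat / respiration frequencies chosen so that no intermodulation
  # product of one subject's own lines falls on the other's heartbeat
  # (the phase nonlinearity mixes heartbeat and respiration lines)
  sc <- radar_scene(list(
    radar_target(1.2, -30, vital_profile(heartbeat_frequency = 1.1)),
    radar_target(1.2, 30, vital_profile(respiration_frequency = 0.26,
                                        heartbeat_frequency = 1.57,
                                        respiration_phase = 2.1))),
    snr_db = 25, duration = 25.6, seed = 2)
  cube <- simulate_cube(sc, cfg)
  rmap <- remove_clutter(range_fft(cube))
  bin <- round(1.2 / cfg$range_bin_width)
  slice <- rmap[bin + 1L, , ]
  # known covariance from the true geometry
  I <- cfg$n_channels
  a <- function(th) exp(2i * pi * 0.5 * (0:(I - 1)) * sinpi(th / 180))
  Rk <- outer(a(-30), Conj(a(-30))) + outer(a(30), Conj(a(30))) +
    diag(1e-4, I)
  f_true <- c(1.1, 1.57)
  for (k in 1:2) {
    th <- c(-30, 30)[k]
    y <- mvdr_separate(slice, th, R = Rk)
    ph <- extract_phase(y, rate = cfg$slow_sampling_rate)
    n <- length(ph$values)
    # Hann-tapered periodogram: keeps the (huge) respiration line from
    # leaking a rectangular-window skirt across the heartbeat band
    hann <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
    X <- Mod(fft(ph$values * hann))[1:(n %/% 2)]
    f <- (0:(n %/% 2 - 1)) / n * cfg$slow_sampling_rate
    own <- max(X[abs(f - f_true[k]) < 0.04])
    other <- max(X[abs(f - f_true[3 - k]) < 0.04])
    expect_gt(20 * log10(own / other), 15)
  }
})
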