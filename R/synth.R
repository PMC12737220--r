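# Synthetic scene simulator: chest displacement, IF data cubes,
# benchmark test signals.

#' Chest-wall displacement of a vital profile
#'
#' Evaluates the physiological displacement model s(t): a respiration tone
#' plus its stated harmonics plus a heartbeat tone,
#' `s(t) = Ar sin(2 pi fr t + phi_r) + sum_h Ar*a_h sin(2 pi h fr t + h phi_r)
#'  + Ah sin(2 pi fh t + phi_h)`.
#'
#' @param vital a [vital_profile()].
#' @param times numeric vector of uniformly spaced sample times, s.
#' @return numeric displacement series, m.
#' @examples
#' v <- vital_profile()
#' s <- chest_displacement(v, seq(0, 10, by = 0.05))
#' @export
chest_displacement <- function(vital, times) {
  stopifnot(inherits(vital, "vital_profile"), is.numeric(times))
  if (length(times) > 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt)))
      stop("times must be uniformly spaced")
  }
  fr <- vital$respiration_frequency
  s <- vital$respiration_amplitude *
    sin(2 * pi * fr * times + vital$respiration_phase)
  H <- vital$respiration_harmonics
  if (nrow(H) > 0) {
    for (r in seq_len(nrow(H))) {
      s <- s + vital$respiration_amplitude * H[r, 2] *
        sin(2 * pi * H[r, 1] * fr * times + H[r, 1] * vital$respiration_phase)
    }
  }
  s + vital$heartbeat_amplitude *
    sin(2 * pi * vital$heartbeat_frequency * times + vital$heartbeat_phase)
}

#' Simulate a raw IF data cube for a scene
#'
#' Generates the complex intermediate-frequency samples of a TDM-MIMO FMCW
#' radar observing the scene, as an M x N x I array (fast time x slow time x
#' virtual channel). Each target l contributes, at fast sample m, chirp n and
#' channel i,
#' `a_l exp(j(2 pi f_IF,l m Ts + 4 pi fc (d0_l + s_l(t_n))/c
#'           + 2 pi d_i sin(theta_l)/lambda))`
#' with beat frequency `f_IF,l = 2 S d0_l / c`. Static clutter reflectors are
#' motionless targets; circular white Gaussian noise is added at the scene's
#' SNR, referenced to the per-sample power of the strongest target tone.
#'
#' @param scene a [radar_scene()].
#' @param config a [radar_config()].
#' @return a `radar_cube`: complex array with `dim = c(M, N, I)` and
#'   attributes `config` and `scene_seed`.
#' @export
simulate_cube <- function(scene, config = radar_config()) {
  stopifnot(inherits(scene, "radar_scene"), inherits(config, "radar_config"))
  M <- config$samples_per_chirp
  N <- as.integer(round(scene$duration * config$slow_sampling_rate))
  if (abs(N - scene$duration * config$slow_sampling_rate) > 1e-9)
    stop("duration * slow_sampling_rate must be an integer number of chirps")
  I <- config$n_channels
  Ts <- 1 / config$fast_sampling_rate
  tn <- (seq_len(N) - 1) / config$slow_sampling_rate
  m <- 0:(M - 1)
  di <- (seq_len(I) - 1) * config$element_spacing

  reflectors <- scene$targets
  if (!is.null(scene$static_clutter)) {
    for (r in seq_len(nrow(scene$static_clutter))) {
      reflectors <- c(reflectors, list(radar_target(
        range = scene$static_clutter[r, 1], azimuth = 0, vital = NULL,
        reflectivity = scene$static_clutter[r, 2])))
    }
  }

  cube <- array(0 + 0i, dim = c(M, N, I))
  amp_max <- 0
  for (tg in reflectors) {
    fIF <- 2 * config$sweep_slope * tg$range / SPEED_OF_LIGHT
    if (fIF >= config$fast_sampling_rate / 2)
      stop(sprintf("target at %.2f m lies beyond the unambiguous range (%.2f m)",
                   tg$range, config$max_range))
    s_t <- if (is.null(tg$vital)) rep(0, N) else chest_displacement(tg$vital, tn)
    fast <- exp(2i * pi * fIF * m * Ts)                       # length M
    slow <- exp(4i * pi * config$carrier_frequency *
                  (tg$range + s_t) / SPEED_OF_LIGHT)          # length N
    chan <- exp(2i * pi * di * sinpi(tg$azimuth / 180) /
                  config$wavelength)                          # length I
    block <- tg$reflectivity * outer(fast, slow)              # M x N
    for (i in seq_len(I)) cube[, , i] <- cube[, , i] + block * chan[i]
    if (!is.null(tg$vital) || length(scene$targets) == 0)
      amp_max <- max(amp_max, tg$reflectivity)
  }
  if (amp_max == 0 && length(reflectors) > 0)
    amp_max <- max(vapply(reflectors, function(t) t$reflectivity, numeric(1)))

  if (is.finite(scene$snr_db) && amp_max > 0) {
    sigma2 <- amp_max^2 / undb(scene$snr_db)
    noise <- with_seed(scene$seed, {
      n <- M * N * I
      complex(real = stats::rnorm(n, sd = sqrt(sigma2 / 2)),
              imaginary = stats::rnorm(n, sd = sqrt(sigma2 / 2)))
    })
    cube <- cube + array(noise, dim = c(M, N, I))
  }
  structure(cube, config = config, scene_seed = scene$seed,
            class = c("radar_cube", "array"))
}

#' Two-tone benchmark test signal
#'
#' The real-valued benchmark input used throughout the frequency-estimator
#' studies: `x[n] = A1 sin(2 pi f1 n / fs) + A2 sin(2 pi f2 n / fs)` for
#' `n = 0 .. NS-1`. Defaults reproduce the printed operating point A1 = 1,
#' A2 = 0.8, f1 = 1.05 Hz, f2 = 1.25 Hz, NS = 200, fs = 20 Hz (FFT
#' resolution 0.1 Hz).
#'
#' @param A1,A2 component amplitudes.
#' @param f1,f2 component frequencies, Hz; must be below `fs / 2`.
#' @param fs sampling frequency, Hz.
#' @param NS number of samples.
#' @return numeric vector of length `NS`.
#' @export
two_tone <- function(A1 = 1, A2 = 0.8, f1 = 1.05, f2 = 1.25, fs = 20,
                     NS = 200L) {
  if (NS <= 0) stop("NS must be positive")
  if (f1 >= fs / 2 || f2 >= fs / 2) stop("tone frequencies must be below fs/2")
  n <- 0:(NS - 1)
  A1 * sin(2 * pi * f1 * n / fs) + A2 * sin(2 * pi * f2 * n / fs)
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Adds real (for real input) or circular complex (for complex input) white
#' Gaussian noise such that the ratio of mean signal power to noise variance
#' is `10^(snr_db/10)`. SNR is referenced to the mean per-sample power of
#' `x` itself.
#'
#' @param x numeric or complex series with nonzero power.
#' @param snr_db target signal-to-noise ratio, dB.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return series of the same length and mode as `x`.
#' @export
add_awgn <- function(x, snr_db, seed = NULL) {
  p <- sig_power(x)
  if (p == 0 && is.finite(snr_db))
    stop("cannot set a finite SNR on a zero-power signal")
  if (!is.finite(snr_db)) return(x)
  sigma2 <- p / undb(snr_db)
  with_seed(seed, {
    if (is.complex(x)) {
      x + complex(real = stats::rnorm(length(x), sd = sqrt(sigma2 / 2)),
                  imaginary = stats::rnorm(length(x), sd = sqrt(sigma2 / 2)))
    } else {
      x + stats::rnorm(length(x), sd = sqrt(sigma2))
    }
  })
}
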