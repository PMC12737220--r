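# Domain types: radar configuration, vital-sign profiles, targets, scenes.

SPEED_OF_LIGHT <- 299792458

#' FMCW radar configuration
#'
#' Bundles the chirp, sampling and (virtual) array-geometry parameters of a
#' TDM-MIMO FMCW radar. Defaults correspond to a 77 GHz automotive-style
#' sensor with a 2x4 TDM-MIMO front end expanded to an 8-element virtual
#' uniform linear array at half-wavelength spacing: sweep slope 70 MHz/us,
#' ADC window 50 us at 4 MHz (200 fast-time samples per chirp), frame period
#' 50 ms (20 Hz slow-time rate).
#'
#' @param carrier_frequency carrier (initial chirp) frequency fc, Hz.
#' @param bandwidth full chirp bandwidth B, Hz.
#' @param sweep_slope chirp sweep slope S, Hz/s.
#' @param fast_sampling_rate ADC fast-time sampling rate, Hz.
#' @param samples_per_chirp number of fast-time (ADC) samples per chirp, M.
#' @param slow_sampling_rate chirp/frame repetition rate, Hz.
#' @param n_tx,n_rx number of transmit / receive antennas; the virtual array
#'   has `n_tx * n_rx` channels.
#' @param element_spacing virtual-element spacing d, m; defaults to half the
#'   carrier wavelength.
#' @return an object of class `radar_config` (a named list), with derived
#'   fields `n_channels`, `wavelength`, `chirp_duration` (ADC window),
#'   `frame_period`, `range_bin_width` (c / (2 S M / fast rate)) and
#'   `max_range` (unambiguous range of the sampled IF band).
#' @examples
#' cfg <- radar_config()
#' cfg$range_bin_width   # ~0.0428 m per range bin
#' @export
radar_config <- function(carrier_frequency = 77e9,
                         bandwidth = 3.99e9,
                         sweep_slope = 70e12,
                         fast_sampling_rate = 4e6,
                         samples_per_chirp = 200L,
                         slow_sampling_rate = 20,
                         n_tx = 2L, n_rx = 4L,
                         element_spacing = NULL) {
  stopifnot(carrier_frequency > 0, bandwidth > 0, sweep_slope > 0,
            fast_sampling_rate > 0, samples_per_chirp >= 2,
            slow_sampling_rate > 0, n_tx >= 1, n_rx >= 1)
  M <- as.integer(samples_per_chirp)
  Tadc <- M / fast_sampling_rate
  if (sweep_slope * Tadc > bandwidth + 1e-6 * bandwidth)
    stop("sweep_slope * ADC window exceeds the chirp bandwidth")
  lambda <- SPEED_OF_LIGHT / carrier_frequency
  d <- if (is.null(element_spacing)) lambda / 2 else element_spacing
  cfg <- list(
    carrier_frequency = carrier_frequency,
    bandwidth = bandwidth,
    sweep_slope = sweep_slope,
    fast_sampling_rate = fast_sampling_rate,
    samples_per_chirp = M,
    slow_sampling_rate = slow_sampling_rate,
    frame_period = 1 / slow_sampling_rate,
    chirp_duration = Tadc,
    n_tx = as.integer(n_tx),
    n_rx = as.integer(n_rx),
    n_channels = as.integer(n_tx) * as.integer(n_rx),
    element_spacing = d,
    wavelength = lambda,
    # range per fast-time DFT bin: c * fs_fast / (2 S M)
    range_bin_width = SPEED_OF_LIGHT * fast_sampling_rate /
      (2 * sweep_slope * M),
    max_range = SPEED_OF_LIGHT * fast_sampling_rate / (4 * sweep_slope)
  )
  class(cfg) <- "radar_config"
  cfg
}

#' @export
print.radar_config <- function(x, ...) {
  cat("FMCW radar configuration\n")
  cat(sprintf("  carrier %.2f GHz, slope %.1f MHz/us, ADC %d pts @ %.1f MHz\n",
              x$carrier_frequency / 1e9, x$sweep_slope / 1e12,
              x$samples_per_chirp, x$fast_sampling_rate / 1e6))
  cat(sprintf("  slow-time rate %.1f Hz, %d x %d MIMO -> %d virtual channels\n",
              x$slow_sampling_rate, x$n_tx, x$n_rx, x$n_channels))
  cat(sprintf("  range bin %.4f m, unambiguous range %.2f m\n",
              x$range_bin_width, x$max_range))
  invisible(x)
}

#' Vital-sign displacement profile
#'
#' Describes the chest-wall displacement of one subject as a respiration tone
#' (with optional integer harmonics) plus a much smaller heartbeat tone.
#' Defaults describe a resting adult: respiration 0.3 Hz at 4 mm with 10 %
#' second- and 2 % third-harmonic content (steady breathing is close to
#' sinusoidal), heartbeat 1.233 Hz (74 bpm) at 0.15 mm.
#'
#' @param respiration_frequency Hz.
#' @param respiration_amplitude peak displacement, m.
#' @param respiration_harmonics two-column matrix (or list of pairs) of
#'   `(integer multiple, relative amplitude)` of the respiration fundamental.
#' @param heartbeat_frequency Hz; must lie in (0.5, 3).
#' @param heartbeat_amplitude peak displacement, m.
#' @param respiration_phase,heartbeat_phase initial phases, rad.
#' @return an object of class `vital_profile`.
#' @export
vital_profile <- function(respiration_frequency = 0.3,
                          respiration_amplitude = 4e-3,
                          respiration_harmonics = cbind(c(2, 3), c(0.10, 0.02)),
                          heartbeat_frequency = 1.233,
                          heartbeat_amplitude = 0.15e-3,
                          respiration_phase = 0,
                          heartbeat_phase = 0) {
  if (is.list(respiration_harmonics))
    respiration_harmonics <- do.call(rbind, respiration_harmonics)
  if (is.null(respiration_harmonics))
    respiration_harmonics <- matrix(numeric(0), ncol = 2)
  respiration_harmonics <- matrix(as.numeric(respiration_harmonics), ncol = 2)
  if (respiration_amplitude < 0 || heartbeat_amplitude < 0 ||
      any(respiration_harmonics[, 2] < 0))
    stop("amplitudes must be non-negative")
  if (heartbeat_amplitude > 0 &&
      (heartbeat_frequency <= 0.5 || heartbeat_frequency >= 3))
    stop("heartbeat_frequency must lie in (0.5, 3) Hz")
  out <- list(respiration_frequency = respiration_frequency,
              respiration_amplitude = respiration_amplitude,
              respiration_harmonics = respiration_harmonics,
              heartbeat_frequency = heartbeat_frequency,
              heartbeat_amplitude = heartbeat_amplitude,
              respiration_phase = respiration_phase,
              heartbeat_phase = heartbeat_phase)
  class(out) <- "vital_profile"
  out
}

#' Ground-truth target
#'
#' @param range radial distance d0 from the radar, m (> 0).
#' @param azimuth azimuth angle theta, degrees, |theta| < 90 (boresight 0,
#'   positive toward increasing virtual-element index).
#' @param vital a [vital_profile()]; `NULL` for a motionless reflector.
#' @param reflectivity dimensionless echo amplitude.
#' @return an object of class `radar_target`.
#' @export
radar_target <- function(range, azimuth = 0, vital = vital_profile(),
                         reflectivity = 1) {
  stopifnot(range > 0, abs(azimuth) < 90, reflectivity >= 0)
  out <- list(range = range, azimuth = azimuth, vital = vital,
              reflectivity = reflectivity)
  class(out) <- "radar_target"
  out
}

#' Synthetic scene description
#'
#' A self-contained description of a simulated monitoring scene: subjects
#' (with vital profiles), optional static clutter reflectors, noise level and
#' duration. Feed to [simulate_cube()].
#'
#' @param targets list of [radar_target()] objects.
#' @param static_clutter two-column matrix (range m, amplitude) of motionless
#'   reflectors, or `NULL`.
#' @param snr_db signal-to-noise ratio, dB, defined as the per-sample power of
#'   the strongest target's IF tone over the complex noise variance. Use
#'   `Inf` for a noiseless cube.
#' @param duration recording length, s; `duration * slow rate` must be an
#'   integer number of chirps.
#' @param seed integer RNG seed for the noise realization.
#' @return an object of class `radar_scene`.
#' @export
radar_scene <- function(targets, static_clutter = NULL, snr_db = 20,
                        duration = 60, seed = 1L) {
  if (inherits(targets, "radar_target")) targets <- list(targets)
  stopifnot(is.list(targets),
            all(vapply(targets, inherits, logical(1), "radar_target")))
  if (!is.null(static_clutter))
    static_clutter <- matrix(as.numeric(static_clutter), ncol = 2)
  out <- list(targets = targets, static_clutter = static_clutter,
              snr_db = snr_db, duration = duration, seed = as.integer(seed))
  class(out) <- "radar_scene"
  out
}

#' @export
print.radar_scene <- function(x, ...) {
  cat(sprintf("radar scene: %d target(s), %d clutter reflector(s), %s dB SNR, %.1f s\n",
              length(x$targets),
              if (is.null(x$static_clutter)) 0L else nrow(x$static_clutter),
              format(x$snr_db), x$duration))
  for (i in seq_along(x$targets)) {
    tg <- x$targets[[i]]
    hr <- if (is.null(tg$vital)) NA_real_ else tg$vital$heartbeat_frequency * 60
    cat(sprintf("  target %d: %.2f m, %+.1f deg, HR %s bpm\n", i, tg$range,
                tg$azimuth, ifelse(is.na(hr), "-", sprintf("%.1f", hr))))
  }
  invisible(x)
}
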