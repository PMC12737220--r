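# Plain-text persistence: scene description files, data-cube container,
# CSV exports.
#
# The cube container is a documented text format (header + one "re im" pair
# per line in column-major (fast, slow, channel) order). It replaces an
# HDF5-style container so that fixtures and round-trips stay plain text.

#' Write / read a scene description file
#'
#' Key/value text format, one `key = value` per line; targets and clutter
#' are indexed (`target1.range`, `clutter1.range`, ...). All vital-profile
#' fields are persisted.
#'
#' @param scene a [radar_scene()].
#' @param path file path.
#' @return `write_scene` returns `path` invisibly; `read_scene` returns a
#'   [radar_scene()].
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "radar_scene"))
  ln <- c("format = radarhr-scene-1",
          sprintf("snr_db = %.10g", scene$snr_db),
          sprintf("duration = %.10g", scene$duration),
          sprintf("seed = %d", scene$seed))
  for (i in seq_along(scene$targets)) {
    tg <- scene$targets[[i]]
    p <- sprintf("target%d", i)
    ln <- c(ln,
            sprintf("%s.range = %.10g", p, tg$range),
            sprintf("%s.azimuth = %.10g", p, tg$azimuth),
            sprintf("%s.reflectivity = %.10g", p, tg$reflectivity))
    v <- tg$vital
    if (!is.null(v)) {
      ln <- c(ln,
        sprintf("%s.respiration_frequency = %.10g", p, v$respiration_frequency),
        sprintf("%s.respiration_amplitude = %.10g", p, v$respiration_amplitude),
        sprintf("%s.respiration_harmonics = %s", p,
                paste(sprintf("%g:%g", v$respiration_harmonics[, 1],
                              v$respiration_harmonics[, 2]), collapse = ",")),
        sprintf("%s.heartbeat_frequency = %.10g", p, v$heartbeat_frequency),
        sprintf("%s.heartbeat_amplitude = %.10g", p, v$heartbeat_amplitude),
        sprintf("%s.respiration_phase = %.10g", p, v$respiration_phase),
        sprintf("%s.heartbeat_phase = %.10g", p, v$heartbeat_phase))
    }
  }
  if (!is.null(scene$static_clutter)) {
    for (i in seq_len(nrow(scene$static_clutter))) {
      ln <- c(ln, sprintf("clutter%d.range = %.10g", i,
                          scene$static_clutter[i, 1]),
              sprintf("clutter%d.amplitude = %.10g", i,
                      scene$static_clutter[i, 2]))
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- do.call(rbind, strsplit(ln, "\\s*=\\s*"))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  if (!identical(unname(vals["format"]), "radarhr-scene-1"))
    stop("not a radarhr scene file")
  get_num <- function(k) as.numeric(vals[[k]])
  i <- 1L
  targets <- list()
  while (sprintf("target%d.range", i) %in% names(vals)) {
    p <- sprintf("target%d", i)
    vital <- NULL
    if (sprintf("%s.heartbeat_frequency", p) %in% names(vals)) {
      hpairs <- strsplit(vals[[sprintf("%s.respiration_harmonics", p)]],
                         ",")[[1]]
      H <- if (length(hpairs) && nzchar(hpairs[1])) {
        do.call(rbind, lapply(strsplit(hpairs, ":"), as.numeric))
      } else NULL
      vital <- vital_profile(
        respiration_frequency = get_num(sprintf("%s.respiration_frequency", p)),
        respiration_amplitude = get_num(sprintf("%s.respiration_amplitude", p)),
        respiration_harmonics = H,
        heartbeat_frequency = get_num(sprintf("%s.heartbeat_frequency", p)),
        heartbeat_amplitude = get_num(sprintf("%s.heartbeat_amplitude", p)),
        respiration_phase = get_num(sprintf("%s.respiration_phase", p)),
        heartbeat_phase = get_num(sprintf("%s.heartbeat_phase", p)))
    }
    targets[[i]] <- radar_target(range = get_num(sprintf("%s.range", p)),
                                 azimuth = get_num(sprintf("%s.azimuth", p)),
                                 vital = vital,
                                 reflectivity = get_num(sprintf("%s.reflectivity", p)))
    i <- i + 1L
  }
  i <- 1L
  clutter <- NULL
  while (sprintf("clutter%d.range", i) %in% names(vals)) {
    clutter <- rbind(clutter, c(get_num(sprintf("clutter%d.range", i)),
                                get_num(sprintf("clutter%d.amplitude", i))))
    i <- i + 1L
  }
  radar_scene(targets, static_clutter = clutter,
              snr_db = get_num("snr_db"), duration = get_num("duration"),
              seed = as.integer(get_num("seed")))
}

#' Write / read a data cube container
#'
#' Plain-text cube container: a header with the axis sizes and the radar
#' configuration, followed by one `re im` pair per complex sample in
#' column-major (fast, slow, channel) order.
#'
#' @param cube `radar_cube` (complex M x N x I array with a `config`
#'   attribute).
#' @param path file path.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns a
#'   `radar_cube`.
#' @export
write_cube <- function(cube, path) {
  d <- dim(cube)
  stopifnot(length(d) == 3)
  cfg <- attr(cube, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("radarhr-cube 1",
               sprintf("dims %d %d %d", d[1], d[2], d[3]),
               sprintf("carrier_frequency %.10g", cfg$carrier_frequency),
               sprintf("sweep_slope %.10g", cfg$sweep_slope),
               sprintf("fast_sampling_rate %.10g", cfg$fast_sampling_rate),
               sprintf("slow_sampling_rate %.10g", cfg$slow_sampling_rate),
               sprintf("n_tx %d", cfg$n_tx),
               sprintf("n_rx %d", cfg$n_rx),
               "data"), con)
  z <- as.vector(cube)
  utils::write.table(cbind(Re(z), Im(z)), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  ln <- readLines(path, n = 20)
  if (!startsWith(ln[1], "radarhr-cube")) stop("not a radarhr cube file")
  hdr_end <- which(ln == "data")[1]
  hdr <- ln[2:(hdr_end - 1)]
  kv <- strsplit(hdr, " ")
  vals <- stats::setNames(lapply(kv, function(p) as.numeric(p[-1])),
                          vapply(kv, `[[`, character(1), 1))
  d <- as.integer(vals$dims)
  cfg <- radar_config(carrier_frequency = vals$carrier_frequency,
                      sweep_slope = vals$sweep_slope,
                      fast_sampling_rate = vals$fast_sampling_rate,
                      samples_per_chirp = d[1],
                      slow_sampling_rate = vals$slow_sampling_rate,
                      n_tx = vals$n_tx, n_rx = vals$n_rx)
  m <- utils::read.table(path, skip = hdr_end)
  z <- complex(real = m[[1]], imaginary = m[[2]])
  structure(array(z, dim = d), config = cfg,
            class = c("radar_cube", "array"))
}

#' Export per-segment HDBS detections as CSV
#'
#' One row per detected cluster: segment, cluster id, selected range bin,
#' estimated range (m) and cluster energy.
#'
#' @param detections list of per-segment [hdbs()] results (as returned by
#'   [detect_ranges()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  rows <- do.call(rbind, lapply(seq_along(detections), function(s) {
    d <- detections[[s]]
    if (nrow(d) == 0) return(NULL)
    data.frame(segment = s, cluster = d$cluster, bin = d$bin,
               range_m = d$range, energy = d$energy)
  }))
  if (is.null(rows))
    rows <- data.frame(segment = integer(0), cluster = integer(0),
                       bin = integer(0), range_m = numeric(0),
                       energy = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
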