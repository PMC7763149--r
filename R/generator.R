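#' Behaviour-regime signal configuration for the synthetic generator
#'
#' Builds the configuration driving the synthetic accelerometer generator.
#' Each behaviour regime is an additive model: the projection of gravity onto
#' the device axes for that posture, plus a sinusoidal oscillation on one axis
#' (the tailbeat or mastication rhythm), plus white Gaussian noise, clipped to
#' the device range. The defaults encode the qualitative signatures of the
#' four-class shark ethogram: rest is near-static and low-variance; swimming
#' carries a rhythmic y-axis tailbeat; vertical swimming pairs a ~90
#' degree pitch shift (gravity moves onto the x axis) with the largest
#' tailbeat amplitude, giving it the highest ODBA; chewing is short bouts of
#' small fast x-axis pulses over a resting posture. Water-column and floor
#' swimming share one parameter block (distinct labels) so the swim-merge
#' test has a true null instance.
#'
#' @param sampling_rate samples per second (Hz).
#' @param session_length session duration in seconds.
#' @param device_range clip range in g (tag records +/- this).
#' @param behaviours named list of per-behaviour blocks; each block has
#'   `baseline_orientation` (unit gravity vector in the device frame),
#'   `noise_sd` (g), `oscillation_axis` ("x","y","z"), `oscillation_freq`
#'   (Hz), `oscillation_amp` (g), `dwell_min`/`dwell_max` (s) and
#'   `relative_frequency` (probability weight). Defaults used when `NULL`.
#' @param include_other also emit `other` and `out_of_camera` events (small
#'   weights) to exercise downstream label filtering. Off by default.
#' @param seed integer master seed for schedule and noise.
#' @return a validated object of class `generator_config`.
#' @export
generator_config <- function(sampling_rate = 10, session_length = 600,
                             device_range = 2.0, behaviours = NULL,
                             include_other = FALSE, seed = 1L) {
  if (is.null(behaviours)) {
    behaviours <- list(
      rest = behaviour_block(c(0, 0, 1), noise_sd = 0.01,
                             oscillation_axis = "y", oscillation_freq = 0.7,
                             oscillation_amp = 0, dwell_min = 10,
                             dwell_max = 120, relative_frequency = 0.35),
      swim_column = behaviour_block(c(0, 0, 1), noise_sd = 0.02,
                                    oscillation_axis = "y",
                                    oscillation_freq = 0.7,
                                    oscillation_amp = 0.2, dwell_min = 10,
                                    dwell_max = 120,
                                    relative_frequency = 0.20),
      swim_floor = behaviour_block(c(0, 0, 1), noise_sd = 0.02,
                                   oscillation_axis = "y",
                                   oscillation_freq = 0.7,
                                   oscillation_amp = 0.2, dwell_min = 10,
                                   dwell_max = 120,
                                   relative_frequency = 0.15),
      vertical_swim = behaviour_block(c(-1, 0, 0), noise_sd = 0.05,
                                      oscillation_axis = "y",
                                      oscillation_freq = 1.2,
                                      oscillation_amp = 0.6, dwell_min = 2,
                                      dwell_max = 10,
                                      relative_frequency = 0.12),
      chew = behaviour_block(c(0, 0, 1), noise_sd = 0.015,
                             oscillation_axis = "x", oscillation_freq = 3,
                             oscillation_amp = 0.1, dwell_min = 1,
                             dwell_max = 6, relative_frequency = 0.18)
    )
    if (include_other) {
      behaviours$other <- behaviour_block(c(0, 0.2, 0.98), noise_sd = 0.1,
                                          oscillation_axis = "z",
                                          oscillation_freq = 0.5,
                                          oscillation_amp = 0.05,
                                          dwell_min = 2, dwell_max = 8,
                                          relative_frequency = 0.04)
      behaviours$out_of_camera <- behaviour_block(c(0, 0, 1),
                                                  noise_sd = 0.02,
                                                  oscillation_axis = "y",
                                                  oscillation_freq = 0.7,
                                                  oscillation_amp = 0.2,
                                                  dwell_min = 5,
                                                  dwell_max = 30,
                                                  relative_frequency = 0.04)
    }
  }
  cfg <- structure(list(sampling_rate = sampling_rate,
                        session_length = session_length,
                        device_range = device_range,
                        behaviours = behaviours,
                        seed = as.integer(seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param baseline_orientation unit gravity vector (length-3) in the device
#'   frame for the posture.
#' @param noise_sd,oscillation_axis,oscillation_freq,oscillation_amp,dwell_min,dwell_max,relative_frequency
#'   per-behaviour signal parameters, see `generator_config`.
#' @export
behaviour_block <- function(baseline_orientation, noise_sd, oscillation_axis,
                            oscillation_freq, oscillation_amp, dwell_min,
                            dwell_max, relative_frequency) {
  list(baseline_orientation = baseline_orientation, noise_sd = noise_sd,
       oscillation_axis = oscillation_axis,
       oscillation_freq = oscillation_freq,
       oscillation_amp = oscillation_amp, dwell_min = dwell_min,
       dwell_max = dwell_max, relative_frequency = relative_frequency)
}

validate_generator_config <- function(cfg) {
  if (cfg$sampling_rate <= 0) stopf("sampling_rate must be > 0")
  if (cfg$device_range <= 0) stopf("device_range must be > 0")
  if (cfg$session_length < 0) stopf("session_length must be >= 0")
  if (length(cfg$behaviours) == 0) stopf("at least one behaviour block")
  for (nm in names(cfg$behaviours)) {
    b <- cfg$behaviours[[nm]]
    if (!nm %in% RAW_LABELS) stopf("unknown behaviour label '%s'", nm)
    if (b$noise_sd < 0) stopf("%s: noise_sd must be >= 0", nm)
    if (!b$oscillation_axis %in% c("x", "y", "z"))
      stopf("%s: oscillation_axis must be x, y or z", nm)
    if (b$oscillation_freq >= cfg$sampling_rate / 2)
      stopf("%s: oscillation_freq must be below the Nyquist rate", nm)
    if (b$dwell_min > b$dwell_max) stopf("%s: dwell_min > dwell_max", nm)
    if (b$dwell_min <= 0) stopf("%s: dwell_min must be > 0", nm)
    if (b$relative_frequency < 0) stopf("%s: negative weight", nm)
    nrm <- sqrt(sum(b$baseline_orientation^2))
    if (abs(nrm - 1) > 1e-6)
      stopf("%s: baseline_orientation must be a unit vector", nm)
  }
  if (sum(vapply(cfg$behaviours, `[[`, 0, "relative_frequency")) <= 0)
    stopf("relative_frequency weights must sum to > 0")
  invisible(cfg)
}

#' Draw a behaviour schedule (dwell-time state sequence)
#'
#' Tiles `[0, session_length]` with behaviour events: labels drawn by
#' `relative_frequency` with no two consecutive identical labels (unless only
#' one label has positive weight), durations uniform on the label's
#' `[dwell_min, dwell_max]`, last event truncated at the session end.
#'
#' @param config a `generator_config`.
#' @return data.frame with columns `event_id,label,start,end` (seconds).
#' @export
sample_schedule <- function(config) {
  validate_generator_config(config)
  L <- config$session_length
  empty <- data.frame(event_id = integer(), label = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (L <= 0) return(empty)
  w <- vapply(config$behaviours, `[[`, 0, "relative_frequency")
  w <- w / sum(w)
  labs <- names(config$behaviours)
  if (L < min(vapply(config$behaviours, `[[`, 0, "dwell_min")))
    warnf("session_length %.3g s is shorter than the smallest dwell_min; %s",
          L, "emitting a single truncated event")
  set.seed(derive_seed(config$seed, 1))
  out <- list()
  t <- 0; prev <- NA_character_; i <- 0L
  while (t < L - 1e-9) {
    i <- i + 1L
    wi <- w
    if (!is.na(prev) && sum(w > 0) > 1) wi[labs == prev] <- 0
    lab <- sample(labs, 1, prob = wi / sum(wi))
    b <- config$behaviours[[lab]]
    dur <- stats::runif(1, b$dwell_min, b$dwell_max)
    out[[i]] <- data.frame(event_id = i, label = lab, start = t,
                           end = min(t + dur, L), stringsAsFactors = FALSE)
    prev <- lab
    t <- t + dur
  }
  do.call(rbind, out)
}

axis_index <- c(x = 1L, y = 2L, z = 3L)

#' Synthesize a tri-axial accelerometer stream from a schedule
#'
#' Per-sample signal = gravity projection of the event's posture + sinusoid
#' on the oscillation axis (phase zero at event onset) + white noise, clipped
#' to the device range. Clipped samples are reported via a message.
#'
#' @param schedule event data.frame from [sample_schedule()].
#' @param config the `generator_config` that produced it.
#' @return an `accel_stream`: data.frame `time,x,y,z` (seconds, g) with a
#'   `sampling_rate` attribute.
#' @export
synthesize_stream <- function(schedule, config) {
  validate_generator_config(config)
  fs <- config$sampling_rate
  if (nrow(schedule) == 0) return(accel_stream(
    data.frame(time = numeric(), x = numeric(), y = numeric(),
               z = numeric()), fs))
  L <- max(schedule$end)
  n <- round(fs * L)
  tt <- (seq_len(n) - 1) / fs
  sig <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  set.seed(derive_seed(config$seed, 2))
  for (k in seq_len(nrow(schedule))) {
    b <- config$behaviours[[schedule$label[k]]]
    idx <- which(tt >= schedule$start[k] - 1e-9 & tt < schedule$end[k] - 1e-9)
    if (length(idx) == 0) next
    base <- matrix(b$baseline_orientation, length(idx), 3, byrow = TRUE)
    osc <- b$oscillation_amp *
      sin(2 * pi * b$oscillation_freq * (tt[idx] - schedule$start[k]))
    base[, axis_index[[b$oscillation_axis]]] <-
      base[, axis_index[[b$oscillation_axis]]] + osc
    noise <- matrix(stats::rnorm(3 * length(idx), sd = b$noise_sd),
                    length(idx), 3)
    sig[idx, ] <- base + noise
  }
  clipped <- sum(abs(sig) > config$device_range)
  if (clipped > 0)
    message(sprintf("synthesize_stream: clipped %d samples at +/-%g g",
                    clipped, config$device_range))
  sig <- pmin(pmax(sig, -config$device_range), config$device_range)
  accel_stream(data.frame(time = tt, x = sig[, 1], y = sig[, 2],
                          z = sig[, 3]), fs)
}

#' Construct/validate an accelerometer stream
#'
#' @param df data.frame with columns `time,x,y,z` (seconds, g), time strictly
#'   increasing on a regular grid of spacing `1/sampling_rate`.
#' @param sampling_rate sampling rate in Hz.
#' @return `df` with class `accel_stream` and a `sampling_rate` attribute.
#' @export
accel_stream <- function(df, sampling_rate) {
  stopifnot(all(c("time", "x", "y", "z") %in% names(df)))
  if (nrow(df) > 1) {
    dt <- diff(df$time)
    if (any(abs(dt - 1 / sampling_rate) > 1e-6))
      stopf("time must advance by 1/sampling_rate (tolerance 1e-6 s)")
  }
  if (nrow(df) && !all(is.finite(as.matrix(df[c("x", "y", "z")]))))
    stopf("non-finite acceleration values")
  structure(df, sampling_rate = sampling_rate,
            class = c("accel_stream", "data.frame"))
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> %d samples at %g Hz (%.1f s)\n", nrow(x),
              attr(x, "sampling_rate"),
              nrow(x) / attr(x, "sampling_rate")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Generate labelled synthetic sessions on disk
#'
#' Writes one accelerometer CSV (`time,x,y,z`; time to 3 decimals, axes in g)
#' and one label CSV (`event_id,label,start,end`) per session, plus a
#' plain-text manifest listing the file pairs. Per-session seeds are derived
#' deterministically from `config$seed`, so regeneration with the same
#' arguments is byte-identical.
#'
#' @param n_sessions number of sessions (>= 1).
#' @param config a `generator_config`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
generate_dataset <- function(n_sessions, config, dir) {
  stopifnot(is_count(n_sessions), n_sessions >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create output directory '%s'", dir)
  manifest <- character(n_sessions)
  for (s in seq_len(n_sessions)) {
    cfg_s <- config
    cfg_s$seed <- derive_seed(config$seed, 100 + s)
    sched <- sample_schedule(cfg_s)
    stream <- synthesize_stream(sched, cfg_s)
    acc_f <- sprintf("session%02d_accel.csv", s)
    lab_f <- sprintf("session%02d_labels.csv", s)
    write_stream_csv(stream, file.path(dir, acc_f))
    write_events_csv(sched, file.path(dir, lab_f))
    manifest[s] <- paste(acc_f, lab_f, sep = "\t")
  }
  mpath <- file.path(dir, "manifest.txt")
  writeLines(manifest, mpath)
  invisible(mpath)
}

write_stream_csv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,x,y,z", con)
  if (nrow(stream))
    writeLines(sprintf("%.3f,%.6f,%.6f,%.6f", stream$time, stream$x,
                       stream$y, stream$z), con)
}

write_events_csv <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("event_id,label,start,end", con)
  if (nrow(events))
    writeLines(sprintf("%d,%s,%.3f,%.3f", events$event_id, events$label,
                       events$start, events$end), con)
}

#' Read a session written by [generate_dataset()]
#'
#' @param accel_path accelerometer CSV (`time,x,y,z`).
#' @param labels_path label CSV (`event_id,label,start,end`).
#' @param sampling_rate sampling rate in Hz; inferred from the time column
#'   when `NULL`.
#' @return list with elements `stream` (an `accel_stream`) and `events`.
#' @export
read_session <- function(accel_path, labels_path, sampling_rate = NULL) {
  acc <- utils::read.csv(accel_path)
  ev <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (is.null(sampling_rate)) {
    if (nrow(acc) < 2) stopf("cannot infer sampling rate from <2 samples")
    sampling_rate <- 1 / stats::median(diff(acc$time))
  }
  list(stream = accel_stream(acc, sampling_rate), events = ev)
}

#' Read every session listed in a dataset manifest
#'
#' @param manifest_path path to `manifest.txt` from [generate_dataset()].
#' @return named list of sessions (`stream` + `events`).
#' @export
read_manifest <- function(manifest_path) {
  dir <- dirname(manifest_path)
  pairs <- strsplit(readLines(manifest_path), "\t")
  out <- lapply(pairs, function(p)
    read_session(file.path(dir, p[1]), file.path(dir, p[2])))
  names(out) <- vapply(pairs, function(p) sub("_accel\\.csv$", "", p[1]), "")
  out
}
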