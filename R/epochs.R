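STAT_CHANNELS <- c("x", "y", "z", "odba", "vedba", "movvar", "energy",
                   "pitch", "roll")
QUANTILE_CHANNELS <- c("odba", "vedba", "movvar", "energy", "pitch", "roll")
MOMENT_STATS <- c("mean", "sd", "min", "max", "skewness", "kurtosis")

#' Names of the 66 epoch summary statistics
#'
#' Six moment statistics (mean, SD, min, max, skewness, kurtosis) for each
#' of the nine channels, plus 10th and 90th percentiles for the six derived
#' movement/posture channels: 9 x 6 + 6 x 2 = 66.
#'
#' @return character vector of length 66, `{channel}_{stat}`.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(STAT_CHANNELS, MOMENT_STATS, paste, sep = "_"))),
    as.vector(t(outer(QUANTILE_CHANNELS, c("q10", "q90"), paste,
                      sep = "_"))))
}

#' Cut single-behaviour epochs from a derived stream
#'
#' Within each behaviour event, consecutive non-overlapping windows of
#' `epoch_seconds * sampling_rate` samples are anchored at the event start;
#' the trailing remainder is discarded, so no epoch ever crosses an event
#' boundary. Events labelled `other` or `out_of_camera` are excluded.
#'
#' @param derived a `derived_stream` from [derive_channels()].
#' @param events data.frame `event_id,label,start,end` (seconds).
#' @param epoch_seconds epoch length in seconds (1 or 2 at 10 Hz);
#'   `epoch_seconds * sampling_rate` must be an integer.
#' @param stride window step in samples; default one full window
#'   (disjoint tiling). Smaller strides give overlapped windows for
#'   sensitivity analysis only.
#' @return data.frame of epochs: `event_id,label,start_index,n_samples`.
#' @export
segment_epochs <- function(derived, events, epoch_seconds, stride = NULL) {
  fs <- attr(derived, "sampling_rate")
  n_ep <- epoch_seconds * fs
  if (abs(n_ep - round(n_ep)) > 1e-9)
    stopf("epoch_seconds x sampling_rate must be an integer sample count")
  n_ep <- as.integer(round(n_ep))
  stride <- as.integer(stride %||% n_ep)
  if (stride < 1) stopf("stride must be >= 1 sample")
  keep <- !(events$label %in% EXCLUDED_LABELS)
  out <- list()
  short <- 0L
  for (k in which(keep)) {
    idx <- which(derived$time >= events$start[k] - 1e-9 &
                   derived$time < events$end[k] - 1e-9)
    if (length(idx) < n_ep) { short <- short + 1L; next }
    starts <- seq(idx[1], idx[length(idx)] - n_ep + 1, by = stride)
    out[[length(out) + 1]] <- data.frame(
      event_id = events$event_id[k], label = events$label[k],
      start_index = starts, n_samples = n_ep, stringsAsFactors = FALSE)
  }
  if (short > 0)
    message(sprintf("segment_epochs: %d event(s) shorter than one epoch",
                    short))
  if (length(out) == 0)
    return(data.frame(event_id = integer(), label = character(),
                      start_index = integer(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Moment statistics of one numeric vector. SD uses the n-1 denominator;
# skewness g1 = m3/m2^1.5 and excess kurtosis g2 = m4/m2^2 - 3 use the
# biased central moments; a constant vector gets sd = skew = kurt = 0.
moment_stats <- function(v) {
  n <- length(v)
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    sk <- 0; ku <- 0; s <- 0
  } else {
    sk <- mean(d^3) / m2^1.5
    ku <- mean(d^4) / m2^2 - 3
    s <- sqrt(sum(d^2) / (n - 1))
  }
  c(mean = m, sd = s, min = min(v), max = max(v), skewness = sk,
    kurtosis = ku)
}

#' Summarise one epoch into its 66 statistics
#'
#' @param epoch one row of the epoch table from [segment_epochs()].
#' @param derived the `derived_stream` the epoch indexes into.
#' @return one-row data.frame: 66 feature columns named `{channel}_{stat}`
#'   plus `label` and `event_id`.
#' @export
summarize_epoch <- function(epoch, derived) {
  rows <- seq(epoch$start_index, length.out = epoch$n_samples)
  if (rows[length(rows)] > nrow(derived)) stopf("epoch overruns the stream")
  vals <- numeric(0)
  for (ch in STAT_CHANNELS)
    vals <- c(vals, stats::setNames(moment_stats(derived[[ch]][rows]),
                                    paste(ch, MOMENT_STATS, sep = "_")))
  for (ch in QUANTILE_CHANNELS) {
    q <- stats::quantile(derived[[ch]][rows], c(0.1, 0.9), names = FALSE,
                         type = 7)
    vals <- c(vals, stats::setNames(q, paste(ch, c("q10", "q90"),
                                             sep = "_")))
  }
  out <- as.data.frame(as.list(vals))
  out$label <- epoch$label
  out$event_id <- epoch$event_id
  out
}

#' Build the epoch feature table for one or more sessions
#'
#' Runs the derive -> segment -> summarise chain over each session and stacks
#' the per-epoch feature vectors. Spans of the stream not covered by the
#' label track are treated as `out_of_camera` (excluded).
#'
#' @param sessions list of sessions, each `list(stream=, events=)` as
#'   returned by [read_session()]/[read_manifest()]; or a manifest path.
#' @param epoch_seconds epoch length in seconds.
#' @param window static-split moving-average window.
#' @param energy_form passed to [derive_channels()].
#' @param stride passed to [segment_epochs()].
#' @return data.frame: 66 feature columns + `label`, `event_id`, `session`.
#' @export
build_feature_table <- function(sessions, epoch_seconds, window = 5,
                                energy_form = "magnitude", stride = NULL) {
  if (is.character(sessions)) sessions <- read_manifest(sessions)
  if (is.null(names(sessions)))
    names(sessions) <- sprintf("session%02d", seq_along(sessions))
  out <- list()
  for (nm in names(sessions)) {
    ses <- sessions[[nm]]
    der <- derive_channels(ses$stream, window = window,
                           energy_form = energy_form)
    epochs <- segment_epochs(der, ses$events, epoch_seconds,
                             stride = stride)
    if (nrow(epochs) == 0) next
    rows <- lapply(seq_len(nrow(epochs)), function(i)
      summarize_epoch(epochs[i, ], der))
    tab <- do.call(rbind, rows)
    tab$session <- nm
    # event ids made globally unique across sessions
    tab$event_id <- paste(nm, tab$event_id, sep = ":")
    out[[nm]] <- tab
  }
  if (length(out) == 0) stopf("no epochs produced from the given sessions")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
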