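#' Construct a multichannel epoch set
#'
#' Container for event-locked sensor (or source) recordings: a
#' trials x channels x samples tensor in microvolts together with the
#' metadata every downstream stage needs (channel labels, sampling rate,
#' epoch window relative to the trigger, interval tag, per-trial task
#' identity and category labels, and the running bad-channel list).
#'
#' @param data Numeric array, trials x channels x samples.
#' @param channel_labels Character vector of unique channel names
#'   (10-5-system names for scalp data).
#' @param fs Sampling rate in Hz.
#' @param window Length-2 numeric, epoch window `(t_start_ms, t_end_ms)`
#'   relative to the trigger; samples cover `[t_start, t_end)` (half-open).
#' @param interval_tag One of `"early"`, `"late"`, `"full"`.
#' @param task_id Per-trial task identifier (recycled if length 1).
#' @param categories List (one element per trial) of category label vectors.
#' @param bad_channels Character vector of channels flagged as bad.
#' @return An object of class `sensor_epochs`.
#' @export
sensor_epochs <- function(data, channel_labels, fs,
                          window = c(0, dim(data)[3] / fs * 1000),
                          interval_tag = "full",
                          task_id = rep(NA_character_, dim(data)[1]),
                          categories = NULL,
                          bad_channels = character(0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_invalid("`data` must be a trials x channels x samples array")
  n_trials <- dim(data)[1]; n_chan <- dim(data)[2]; n_samp <- dim(data)[3]
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != n_chan)
    stop_invalid("%d channel labels for %d channels", length(channel_labels), n_chan)
  if (anyDuplicated(channel_labels))
    stop_invalid("channel labels must be unique")
  if (!interval_tag %in% c("early", "late", "full"))
    stop_invalid("`interval_tag` must be early/late/full")
  window <- as.numeric(window)
  expected <- round((window[2] - window[1]) * fs / 1000)
  if (expected != n_samp)
    stop_invalid("window %s ms at %g Hz implies %d samples, data has %d",
                 paste(window, collapse = ".."), fs, expected, n_samp)
  if (length(task_id) == 1L) task_id <- rep(task_id, n_trials)
  if (length(task_id) != n_trials)
    stop_invalid("`task_id` must have one entry per trial")
  if (is.null(categories)) categories <- rep(list(character(0)), n_trials)
  if (length(categories) != n_trials)
    stop_invalid("`categories` must have one entry per trial")
  structure(
    list(data = data, channel_labels = channel_labels, fs = fs,
         window = window, interval_tag = interval_tag,
         task_id = as.character(task_id), categories = categories,
         bad_channels = as.character(bad_channels)),
    class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sensor_epochs> %d trial(s) x %d channel(s) x %d sample(s) @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  window %g..%g ms (%s)", x$window[1], x$window[2], x$interval_tag))
  if (length(x$bad_channels))
    cat(sprintf(", bad: %s", paste(x$bad_channels, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
dim.sensor_epochs <- function(x) dim(x$data)

# replace the data tensor, keeping metadata consistent
replace_epoch_data <- function(epochs, data, window = epochs$window,
                               interval_tag = epochs$interval_tag) {
  sensor_epochs(data, epochs$channel_labels, epochs$fs, window = window,
                interval_tag = interval_tag, task_id = epochs$task_id,
                categories = epochs$categories,
                bad_channels = epochs$bad_channels)
}
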