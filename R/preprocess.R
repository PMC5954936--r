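#' Design a zero-phase windowed-sinc FIR band-pass kernel
#'
#' Hamming-windowed sinc design, built as the difference of two low-pass
#' kernels with -6 dB points at the band edges. The transition width is 25%
#' of each cutoff frequency and the kernel length follows the Hamming rule
#' (normalized transition ~ 3.3 / N), forced odd so the kernel is exactly
#' symmetric (linear phase).
#'
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return Numeric kernel of odd length with attribute `delay` (group delay
#'   in samples).
#' @keywords internal
design_fir_bandpass <- function(low, high, fs) {
  if (!(0 < low && low < high && high < fs / 2))
    stop_invalid("band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
                 low, high, fs / 2)
  trans <- 0.25 * min(low, high)            # Hz; narrowest transition governs
  n <- ceiling(3.3 * fs / trans)
  if (n %% 2 == 0) n <- n + 1
  mid <- (n - 1) / 2
  t <- seq_len(n) - 1 - mid
  lowpass <- function(fc) {
    h <- 2 * fc / fs * sinc_(2 * fc / fs * t)
    h * hamming_(n)
  }
  h <- lowpass(high) - lowpass(low)
  # normalize to unit gain at the band center
  f0 <- sqrt(low * high)
  gain <- Mod(sum(h * exp(-2i * pi * f0 / fs * (seq_len(n) - 1))))
  h <- h / gain
  attr(h, "delay") <- mid
  h
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
hamming_ <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Zero-phase FIR band-pass filtering
#'
#' Filters each channel with the symmetric windowed-sinc kernel of
#' [design_fir_bandpass()]; the edges are padded by reflection and the
#' group delay compensated, so the output has zero net phase shift and the
#' same length as the input.
#'
#' @param data Numeric vector or channels x samples matrix.
#' @param low,high Pass-band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return Filtered data with the shape of the input.
#' @export
bandpass_fir <- function(data, low, high, fs) {
  h <- design_fir_bandpass(low, high, fs)
  vec <- is.null(dim(data))
  x <- if (vec) matrix(data, nrow = 1) else as.matrix(data)
  n <- ncol(x)
  pad <- attr(h, "delay")
  if (pad > n - 1)
    stop_invalid("recording too short (%d samples) for the %d-tap kernel; need > %d samples",
                 n, length(h), pad)
  out <- t(apply(x, 1, function(ch) {
    padded <- c(rev(ch[2:(pad + 1)]), ch, rev(ch[(n - pad):(n - 1)]))
    full <- fft_convolve(padded, h)
    full[2 * pad + seq_len(n)]
  }))
  if (vec) drop(out) else out
}

# linear convolution via FFT, returns length(x) + length(h) - 1
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(x, rep(0, nf - length(x)))) *
                  stats::fft(c(h, rep(0, nf - length(h)))), inverse = TRUE))[seq_len(n)] / nf
}

#' Integer-factor downsampling
#'
#' Retains every k-th sample (k = fs / target_fs). Assumes content above the
#' new Nyquist has already been removed by the band-pass stage.
#'
#' @param data Numeric vector or channels x samples matrix sampled at `fs`.
#' @param fs Original sampling rate in Hz.
#' @param target_fs New sampling rate; must divide `fs`.
#' @return Decimated data (same shape convention as the input).
#' @export
downsample <- function(data, fs, target_fs) {
  if (fs %% target_fs != 0)
    stop_invalid("fs = %g is not an integer multiple of target_fs = %g", fs, target_fs)
  k <- fs %/% target_fs
  if (is.null(dim(data))) data[seq(1, length(data), by = k)]
  else data[, seq(1, ncol(data), by = k), drop = FALSE]
}

#' Map trigger times to sample indices on a given clock
#'
#' @param triggers_s Trigger onset times in seconds.
#' @param fs Sampling rate in Hz.
#' @return Zero-based sample indices (`round(t * fs)`).
#' @export
trigger_samples <- function(triggers_s, fs) as.integer(round(triggers_s * fs))

#' Extract event-locked epochs from a continuous recording
#'
#' Cuts one epoch per trigger covering the half-open window
#' `[t_min_ms, t_max_ms)` relative to the trigger (0-based sample indexing);
#' each epoch channel is mean-centred at extraction, since the downstream
#' autoregressive modelling assumes zero-mean series. Triggers whose window
#' exceeds the recording are dropped with a warning and counted in the
#' `n_dropped` attribute.
#'
#' @param data Channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param triggers_s Trigger onset times in seconds.
#' @param t_min_ms,t_max_ms Epoch window in ms relative to the trigger.
#' @param channel_labels Channel names (default "ch01", ...).
#' @param task_id Optional per-trigger task ids.
#' @param demean Remove the per-epoch channel mean (default TRUE).
#' @return A `sensor_epochs` object with attribute `n_dropped`.
#' @export
extract_epochs <- function(data, fs, triggers_s, t_min_ms = -2000,
                           t_max_ms = 5000, channel_labels = NULL,
                           task_id = NULL, demean = TRUE) {
  data <- as.matrix(data)
  n <- ncol(data)
  n_samp <- round((t_max_ms - t_min_ms) * fs / 1000)
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  if (is.null(task_id)) task_id <- rep(NA_character_, length(triggers_s))
  starts <- trigger_samples(triggers_s, fs) + round(t_min_ms * fs / 1000)
  keep <- starts >= 0 & (starts + n_samp) <= n
  if (any(!keep))
    warning(sprintf("dropped %d epoch(s) exceeding recording bounds", sum(!keep)))
  starts <- starts[keep]; task_id <- task_id[keep]
  out <- array(0, dim = c(length(starts), nrow(data), n_samp))
  for (i in seq_along(starts)) {
    slice <- data[, starts[i] + seq_len(n_samp), drop = FALSE]  # 0-based start
    if (demean) slice <- slice - rowMeans(slice)
    out[i, , ] <- slice
  }
  ep <- sensor_epochs(out, channel_labels, fs, window = c(t_min_ms, t_max_ms),
                      task_id = task_id,
                      categories = rep(list(character(0)), length(starts)))
  attr(ep, "n_dropped") <- sum(!keep)
  ep
}

#' Split epochs into early and late imagery intervals
#'
#' Early covers -1000..+2000 ms around the trigger (imagery onset), late
#' +2000..+5000 ms (continuous imagery); windows are half-open so the
#' +2000 ms boundary sample belongs to the late interval only.
#'
#' @param epochs A `sensor_epochs` spanning at least -1000..+5000 ms.
#' @param early_ms,late_ms Interval windows in ms.
#' @return List with elements `early` and `late` (both `sensor_epochs`).
#' @export
split_intervals <- function(epochs, early_ms = c(-1000, 2000),
                            late_ms = c(2000, 5000)) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  w <- epochs$window
  if (w[1] > min(early_ms) || w[2] < max(late_ms))
    stop_invalid("epoch window %g..%g ms does not span %g..%g ms",
                 w[1], w[2], min(early_ms), max(late_ms))
  slice <- function(win, tag) {
    i0 <- round((win[1] - w[1]) * epochs$fs / 1000)
    ns <- round((win[2] - win[1]) * epochs$fs / 1000)
    replace_epoch_data(epochs, epochs$data[, , i0 + seq_len(ns), drop = FALSE],
                       window = win, interval_tag = tag)
  }
  list(early = slice(early_ms, "early"), late = slice(late_ms, "late"))
}

#' Flag bad channels by robust statistics
#'
#' A reproducible surrogate for visual screening: a channel is flagged when
#' the robust z-score (median/MAD across channels) of its standard deviation
#' or of the absolute slope of a linear drift fit exceeds `z_threshold`.
#' A user-supplied bad list is always unioned into the result.
#'
#' @param data Channels x samples matrix (continuous recording).
#' @param channel_labels Channel names.
#' @param z_threshold Robust z cutoff (default 5).
#' @param user_bad Channels to flag unconditionally.
#' @return Character vector of bad channel labels.
#' @export
detect_bad_channels <- function(data, channel_labels = NULL, z_threshold = 5,
                                user_bad = character(0)) {
  data <- as.matrix(data)
  if (nrow(data) < 8)
    stop_invalid("need at least 8 channels for robust screening")
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  t_idx <- seq_len(ncol(data))
  sds <- apply(data, 1, stats::sd)
  slopes <- abs(apply(data, 1, function(ch) stats::cov(ch, t_idx) / stats::var(t_idx)))
  rz <- function(v) abs(v - stats::median(v)) / max(stats::mad(v), 1e-12)
  flagged <- channel_labels[rz(sds) > z_threshold | rz(slopes) > z_threshold]
  sort(union(flagged, user_bad))
}
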