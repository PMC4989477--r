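# Preprocessing: zero-phase bandpass, detrending/baseline correction and
# event-anchored train averaging.

#' Zero-phase Butterworth bandpass filter
#'
#' Filters each channel with a Butterworth bandpass of the given order,
#' applied forward and backward (zero phase, no phase distortion). The
#' effective magnitude response is the squared single-pass Butterworth
#' magnitude. Edges are handled by odd-symmetric reflection padding of
#' three times the filter length, so that start-up transients decay
#' outside the data. Filtering is meant to be applied to the continuous
#' recording, before epoching.
#'
#' @param x A `meg_recording`, a channels-by-samples matrix, or a
#'   numeric vector.
#' @param low_hz,high_hz Band edges in Hz (defaults 2 and 30).
#' @param order Butterworth order per edge (default 4).
#' @param sfreq Sampling rate in Hz; taken from the recording when `x`
#'   is a `meg_recording`.
#' @return Object of the same shape as `x`, filtered.
#' @export
bandpass <- function(x, low_hz = 2, high_hz = 30, order = 4, sfreq = NULL) {
  UseMethod("bandpass")
}

#' @export
bandpass.meg_recording <- function(x, low_hz = 2, high_hz = 30, order = 4,
                                   sfreq = NULL) {
  x$data <- bandpass(x$data, low_hz, high_hz, order, sfreq = x$sfreq)
  x$meta$bandpass <- c(low_hz, high_hz)
  x
}

#' @export
bandpass.matrix <- function(x, low_hz = 2, high_hz = 30, order = 4,
                            sfreq = NULL) {
  flt <- design_bandpass(low_hz, high_hz, order, sfreq)
  out <- t(apply(x, 1, filtfilt_padded, b = flt$b, a = flt$a))
  dimnames(out) <- dimnames(x)
  out
}

#' @export
bandpass.numeric <- function(x, low_hz = 2, high_hz = 30, order = 4,
                             sfreq = NULL) {
  flt <- design_bandpass(low_hz, high_hz, order, sfreq)
  filtfilt_padded(x, flt$b, flt$a)
}

#' @keywords internal
design_bandpass <- function(low_hz, high_hz, order, sfreq) {
  if (is.null(sfreq)) stop("sfreq is required when filtering raw arrays")
  nyq <- sfreq / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("band edges must satisfy 0 < low < high < Nyquist (%g Hz)", nyq))
  }
  flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  list(b = flt$b, a = flt$a)
}

# Forward-backward IIR filtering with odd-symmetric edge padding.
#' @keywords internal
filtfilt_padded <- function(x, b, a, pad_factor = 3) {
  n <- length(x)
  p <- min(n - 1, pad_factor * (max(length(a), length(b)) - 1))
  xp <- c(2 * x[1] - rev(x[seq(2, p + 1)]),
          x,
          2 * x[n] - rev(x[seq(n - p, n - 1)]))
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(p + 1):(p + n)])
}

#' Analytic magnitude response of the zero-phase bandpass
#'
#' Closed-form squared Butterworth magnitude of the forward-backward
#' bandpass, treating the two band edges as independent low-/high-pass
#' prototypes: `|H(f)|^2` with
#' `|H| = 1/sqrt(1+(f/high)^(2k)) * 1/sqrt(1+(low/f)^(2k))` for order
#' `k`. Used as the analytic reference for the implemented filter.
#'
#' @param f Frequencies in Hz.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order.
#' @return Expected amplitude gain of the zero-phase filter at `f`.
#' @export
butter_bandpass_gain <- function(f, low_hz = 2, high_hz = 30, order = 4) {
  h <- 1 / sqrt(1 + (f / high_hz)^(2 * order)) /
    sqrt(1 + (low_hz / f)^(2 * order))
  h^2
}

#' Linear detrend and baseline correction
#'
#' Per channel, removes the least-squares line fitted over the whole
#' block, then subtracts the mean over the baseline window so that the
#' baseline-window mean of the output is zero.
#'
#' @param x An `averaged_block` or a channels-by-samples matrix.
#' @param baseline Integer sample indices of the baseline window. For an
#'   `averaged_block` this defaults to the pre-onset segment.
#' @return Object of the same shape as `x`, corrected.
#' @export
detrend_baseline <- function(x, baseline = NULL) {
  UseMethod("detrend_baseline")
}

#' @export
detrend_baseline.averaged_block <- function(x, baseline = NULL) {
  if (is.null(baseline)) baseline <- seq_len(x$baseline_samples)
  x$data <- detrend_baseline(x$data, baseline)
  x
}

#' @export
detrend_baseline.matrix <- function(x, baseline = NULL) {
  n <- ncol(x)
  if (is.null(baseline)) baseline <- seq_len(n)
  baseline <- as.integer(baseline)
  if (!length(baseline)) stop("baseline window must not be empty")
  if (any(baseline < 1) || any(baseline > n)) {
    stop("baseline window must lie inside the data extent")
  }
  tc <- seq_len(n) - (n + 1) / 2
  slope <- as.numeric(x %*% tc) / sum(tc^2)
  x <- x - outer(slope, tc)
  x - rowMeans(x[, baseline, drop = FALSE])
}

#' @export
detrend_baseline.numeric <- function(x, baseline = NULL) {
  drop(detrend_baseline(matrix(x, nrow = 1), baseline))
}

#' Epoch a block into trains and average
#'
#' Extracts every stimulation train from 500 ms before its first flash
#' to 3 s after the end of its last flash period, using the recorded
#' event markers (so fractional-sample period drift never accumulates),
#' and averages across trains sample by sample.
#'
#' @param recording A `meg_recording` of one frequency block, with flash
#'   (code 1), train-onset (code 2) and train-end (code 3) events.
#' @param protocol The session's [stim_protocol()].
#' @param multiplier Stimulation multiplier of the block; defaults to
#'   the recording's metadata.
#' @param pre_s,post_s Pre-onset baseline and post-stimulation window in
#'   seconds (defaults 0.5 and 3).
#' @return An `averaged_block` with the train-averaged data, the 40
#'   flash onsets relative to the averaged trace, and
#'   `n_trains_averaged`.
#' @export
epoch_and_average <- function(recording, protocol,
                              multiplier = recording$meta$multiplier,
                              pre_s = 0.5, post_s = 3) {
  stopifnot(inherits(recording, "meg_recording"))
  if (is.null(multiplier)) stop("multiplier not given and absent from recording metadata")
  sf <- recording$sfreq
  f <- protocol$alpha_hz * multiplier
  period <- round(sf / f)
  ev <- recording$events
  onsets <- ev$sample[ev$code == 2L]
  flashes <- ev$sample[ev$code == 1L]
  if (!length(onsets) || !length(flashes)) {
    stop("recording contains no train-onset/flash events for this block")
  }
  n_flash <- protocol$flashes_per_train
  # assign flashes to trains
  train_of <- findInterval(flashes, onsets)
  counts <- tabulate(train_of, nbins = length(onsets))
  if (any(counts != n_flash)) {
    stop(sprintf("trains of unequal length: expected %d flashes per train, got [%s]",
                 n_flash, paste(unique(counts), collapse = ", ")))
  }
  pre <- round(pre_s * sf)
  post <- round(post_s * sf)
  first_flash <- flashes[match(seq_along(onsets), train_of)]
  last_flash <- flashes[length(flashes) - match(seq_along(onsets), rev(train_of)) + 1]
  starts <- first_flash - pre
  ends <- last_flash + period + post
  win_len <- min(ends - starts) + 1L
  if (any(starts < 1) || any(starts + win_len - 1L > ncol(recording$data))) {
    stop("train windows exceed the recording extent; simulate a longer lead-in/rest")
  }
  acc <- matrix(0, nrow(recording$data), win_len)
  for (k in seq_along(starts)) {
    acc <- acc + recording$data[, starts[k]:(starts[k] + win_len - 1L), drop = FALSE]
  }
  avg <- acc / length(starts)
  # flash onsets relative to the averaged trace (consensus across trains)
  rel <- matrix(flashes - starts[train_of], nrow = n_flash)
  flash_onsets <- round(rowMeans(rel)) + 1L
  n_avg <- recording$meta$represents_average_of
  if (is.null(n_avg) || is.na(n_avg)) n_avg <- length(starts)
  structure(list(
    data = avg, sfreq = sf, multiplier = multiplier, stim_freq_hz = f,
    flash_onsets = flash_onsets, period_samples = period,
    baseline_samples = pre, n_trains_averaged = as.integer(n_avg),
    layout = recording$layout, meta = recording$meta
  ), class = "averaged_block")
}

#' @export
print.averaged_block <- function(x, ...) {
  cat(sprintf("Averaged block: %.2f x alpha (%.2f Hz), %d channels x %d samples, %d trains averaged\n",
              x$multiplier, x$stim_freq_hz, nrow(x$data), ncol(x$data),
              x$n_trains_averaged))
  invisible(x)
}
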