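# Frequency-domain analysis: FFT amplitude spectra, resting alpha
# estimation, alpha peak ratios and the two-rule entrainment classifier.

#' Amplitude spectrum of a channel subset
#'
#' Computes the one-sided FFT amplitude spectrum of each channel over a
#' sample window with a rectangular taper, zero-padded to the next power
#' of two, and averages the amplitudes over the subset. The amplitude
#' convention is `2*|X|/N` with `N` the (unpadded) window length, so a
#' unit sinusoid at a bin frequency has amplitude 1. Power is
#' amplitude squared.
#'
#' @param data Channels-by-samples matrix (single channel type: the
#'   amplitudes are in channel units).
#' @param sfreq Sampling rate in Hz.
#' @param window Integer sample indices of the analysis window.
#' @param pad_pow2 Zero-pad to the next power of two (default TRUE); the
#'   peak frequency is then read off the padded grid.
#' @return A `meg_spectrum`: list with `freqs`, `amplitude`, `power`,
#'   `n_window`, `n_fft`, `resolution_hz` (padded grid) and
#'   `raw_resolution_hz` (`sfreq/n_window`).
#' @export
amplitude_spectrum <- function(data, sfreq, window = seq_len(ncol(data)),
                               pad_pow2 = TRUE) {
  if (is.numeric(data) && is.null(dim(data))) data <- matrix(data, nrow = 1)
  window <- as.integer(window)
  stopifnot(length(window) >= 2, all(window >= 1), all(window <= ncol(data)))
  x <- data[, window, drop = FALSE]
  n <- ncol(x)
  nfft <- if (pad_pow2) next_pow2(n) else n
  amp <- matrix(0, nrow(x), nfft)
  for (c in seq_len(nrow(x))) {
    amp[c, ] <- Mod(stats::fft(c(x[c, ], numeric(nfft - n))))
  }
  half <- seq_len(floor(nfft / 2) + 1)
  a <- 2 * colMeans(amp)[half] / n
  a[1] <- a[1] / 2                          # DC carries no factor 2
  freqs <- (half - 1) * sfreq / nfft
  structure(list(freqs = freqs, amplitude = a, power = a^2,
                 n_window = n, n_fft = nfft,
                 resolution_hz = sfreq / nfft,
                 raw_resolution_hz = sfreq / n,
                 window = range(window)),
            class = "meg_spectrum")
}

#' Stimulation-window spectrum of an averaged block
#'
#' Spectrum over the interval from the first flash to the end of the
#' 40th flash period, averaged over a channel subset (by default the
#' occipital gradiometers). Subsets mixing magnetometers and
#' gradiometers are rejected: fT and fT/cm cannot be averaged.
#'
#' @param block An `averaged_block`.
#' @param subset Channel names or indices; default occipital
#'   gradiometers.
#' @return A `meg_spectrum` (see [amplitude_spectrum()]).
#' @export
compute_spectrum <- function(block, subset = NULL) {
  stopifnot(inherits(block, "averaged_block"))
  idx <- resolve_subset(block$layout, subset)
  window <- seq(block$flash_onsets[1],
                block$flash_onsets[length(block$flash_onsets)] + block$period_samples - 1L)
  spec <- amplitude_spectrum(block$data[idx, , drop = FALSE], block$sfreq, window)
  spec$channel_subset <- block$layout$name[idx]
  spec
}

#' @keywords internal
resolve_subset <- function(layout, subset) {
  if (is.null(subset)) {
    idx <- occipital_gradiometers(layout)
  } else if (is.character(subset)) {
    idx <- match(subset, layout$name)
    if (anyNA(idx)) stop("unknown channel names in subset")
  } else {
    idx <- as.integer(subset)
  }
  if (!length(idx)) stop("channel subset must not be empty")
  if (length(unique(layout$type[idx])) > 1) {
    stop("channel subset mixes magnetometers and gradiometers (unit mismatch)")
  }
  idx
}

#' Estimate the individual resting alpha frequency
#'
#' Peak frequency of the occipital-gradiometer amplitude spectrum of the
#' resting segment within the search band. The peak must be a local
#' maximum of the spectrum and exceed `min_peak_ratio` times the median
#' 2--30 Hz amplitude; otherwise the estimate is flagged as not
#' detected rather than silently extrapolated.
#'
#' @param recording The resting-state `meg_recording` (>= 10 s).
#' @param band Search band in Hz (default 7--13).
#' @param subset Channel subset (default occipital gradiometers).
#' @param min_peak_ratio Peak prominence criterion (default 2).
#' @return An `alpha_estimate`: list with `alpha_hz`, `amplitude`,
#'   `detected` and `reason`.
#' @export
estimate_resting_alpha <- function(recording, band = c(7, 13), subset = NULL,
                                   min_peak_ratio = 2) {
  stopifnot(inherits(recording, "meg_recording"))
  if (ncol(recording$data) / recording$sfreq < 10) {
    stop("resting segment must be at least 10 s long")
  }
  idx <- resolve_subset(recording$layout, subset)
  spec <- amplitude_spectrum(recording$data[idx, , drop = FALSE], recording$sfreq)
  in_band <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  lm_idx <- intersect(local_maxima(spec$amplitude), in_band)
  floor_amp <- stats::median(spec$amplitude[spec$freqs >= 2 & spec$freqs <= 30])
  if (!length(lm_idx)) {
    return(structure(list(alpha_hz = NA_real_, amplitude = NA_real_,
                          detected = FALSE, reason = "no local maximum in band"),
                     class = "alpha_estimate"))
  }
  best <- lm_idx[which.max(spec$amplitude[lm_idx])]
  if (spec$amplitude[best] < min_peak_ratio * floor_amp) {
    return(structure(list(alpha_hz = spec$freqs[best],
                          amplitude = spec$amplitude[best],
                          detected = FALSE, reason = "peak not prominent above spectral floor"),
                     class = "alpha_estimate"))
  }
  structure(list(alpha_hz = spec$freqs[best], amplitude = spec$amplitude[best],
                 detected = TRUE, reason = "ok"),
            class = "alpha_estimate")
}

#' Alpha peak ratio between stimulation and rest
#'
#' Ratio of the alpha-band peak amplitude during stimulation to the
#' resting-state alpha peak amplitude, at the identified individual
#' alpha frequency.
#'
#' @param stim_spec,rest_spec `meg_spectrum` objects sharing the same
#'   frequency resolution (the rest spectrum is computed over a window
#'   of the same length as the 1.00 x alpha stimulation window).
#' @param alpha_hz Identified individual alpha frequency.
#' @param tol_hz Half-width of the alpha search interval (default 1 Hz).
#' @param check_resolution Require identical frequency resolution
#'   (default TRUE). The resting window is matched to the 1.00 x alpha
#'   stimulation window; spectra of other multipliers have their own
#'   window lengths, and the amplitude convention is window-invariant,
#'   so the check is relaxed for them.
#' @return List with `ratio`, `stim_amp`, `rest_amp`, `alpha_hz`.
#' @export
alpha_peak_ratio <- function(stim_spec, rest_spec, alpha_hz, tol_hz = 1,
                             check_resolution = TRUE) {
  stopifnot(inherits(stim_spec, "meg_spectrum"), inherits(rest_spec, "meg_spectrum"))
  if (check_resolution &&
      abs(stim_spec$resolution_hz - rest_spec$resolution_hz) > 1e-9) {
    stop("stimulation and rest spectra must share the same frequency resolution")
  }
  peak_near <- function(spec) {
    i <- which(spec$freqs >= alpha_hz - tol_hz & spec$freqs <= alpha_hz + tol_hz)
    if (!length(i)) stop("alpha frequency outside the spectrum range")
    max(spec$amplitude[i])
  }
  rest_amp <- peak_near(rest_spec)
  if (rest_amp <= 0) stop("resting alpha peak amplitude is zero")
  stim_amp <- peak_near(stim_spec)
  list(ratio = stim_amp / rest_amp, stim_amp = stim_amp,
       rest_amp = rest_amp, alpha_hz = alpha_hz)
}

#' Two-rule frequency-entrainment classifier
#'
#' Finds the highest spectral peak within +/- `search_hz` of the
#' stimulation frequency (the response frequency) and classifies the
#' block as entrained when (1) the response frequency lies within one
#' non-padded frequency bin of the stimulation frequency or one of its
#' harmonics, and (2) its amplitude exceeds `threshold_frac` of the
#' maximum peak found across the whole cohort.
#'
#' @param spectrum A `meg_spectrum` of the block.
#' @param stim_freq_hz Stimulation frequency in Hz.
#' @param cohort_max_amp Maximum per-spectrum peak amplitude over the
#'   whole cohort (all subjects and multipliers), computed beforehand.
#' @param search_hz Half-width of the response search window (default 2).
#' @param harmonics Harmonic orders accepted by the frequency rule.
#' @param threshold_frac Amplitude rule fraction (default 0.2).
#' @return An `entrainment_result`: list with `response_freq_hz`,
#'   `response_amp`, `threshold_amp`, `entrained` and `rule_trace`.
#' @export
classify_entrainment <- function(spectrum, stim_freq_hz, cohort_max_amp,
                                 search_hz = 2, harmonics = 1:3,
                                 threshold_frac = 0.2) {
  stopifnot(inherits(spectrum, "meg_spectrum"), cohort_max_amp > 0)
  lo <- stim_freq_hz - search_hz
  hi <- stim_freq_hz + search_hz
  if (lo < min(spectrum$freqs) - 1e-9 || hi > max(spectrum$freqs) + 1e-9) {
    stop("stimulation frequency +/- search window falls outside the spectrum range")
  }
  win <- which(spectrum$freqs >= lo & spectrum$freqs <= hi)
  cand <- intersect(local_maxima(spectrum$amplitude), win)
  if (!length(cand)) cand <- win
  amps <- spectrum$amplitude[cand]
  best_amp <- max(amps)
  ties <- cand[amps >= best_amp * (1 - 1e-12)]
  best <- ties[which.min(abs(spectrum$freqs[ties] - stim_freq_hz))]
  response_freq <- spectrum$freqs[best]
  response_amp <- spectrum$amplitude[best]
  freq_match <- any(abs(response_freq - harmonics * stim_freq_hz) <=
                      spectrum$raw_resolution_hz + 1e-9)
  threshold_amp <- threshold_frac * cohort_max_amp
  amp_above <- response_amp > threshold_amp
  structure(list(
    stim_freq_hz = stim_freq_hz,
    response_freq_hz = response_freq,
    response_amp = response_amp,
    threshold_amp = threshold_amp,
    entrained = freq_match && amp_above,
    rule_trace = list(freq_match = freq_match, amp_above = amp_above)
  ), class = "entrainment_result")
}

#' Group statistics on alpha peak ratios
#'
#' Per multiplier, a one-sample t-test of the cohort's alpha peak ratios
#' against the null mean of 1 (alpha activity unchanged by
#' stimulation), reporting both one-sided alternatives; plus pairwise
#' paired t-tests between multipliers with Holm correction.
#'
#' @param ratios Data frame with columns `subject`, `multiplier`,
#'   `ratio` (>= 2 subjects per multiplier).
#' @param pairwise Compute the pairwise paired tests (default TRUE).
#' @return List with `per_multiplier` and `pairwise` data frames.
#' @export
test_ratios <- function(ratios, pairwise = TRUE) {
  stopifnot(all(c("subject", "multiplier", "ratio") %in% names(ratios)))
  mults <- sort(unique(ratios$multiplier))
  per <- do.call(rbind, lapply(mults, function(m) {
    x <- ratios$ratio[ratios$multiplier == m]
    if (length(x) < 2) stop("need >= 2 subjects per multiplier")
    if (stats::sd(x) == 0) {
      return(data.frame(multiplier = m, n = length(x), mean_ratio = mean(x),
                        t = NA_real_, p_greater = NA_real_, p_less = NA_real_,
                        degenerate = TRUE))
    }
    tt <- stats::t.test(x, mu = 1)
    data.frame(multiplier = m, n = length(x), mean_ratio = mean(x),
               t = unname(tt$statistic),
               p_greater = stats::pt(unname(tt$statistic), tt$parameter, lower.tail = FALSE),
               p_less = stats::pt(unname(tt$statistic), tt$parameter, lower.tail = TRUE),
               degenerate = FALSE)
  }))
  pw <- NULL
  if (pairwise && length(mults) > 1) {
    combs <- utils::combn(mults, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      m1 <- combs[1, j]; m2 <- combs[2, j]
      d1 <- ratios[ratios$multiplier == m1, c("subject", "ratio")]
      d2 <- ratios[ratios$multiplier == m2, c("subject", "ratio")]
      mg <- merge(d1, d2, by = "subject")
      diffs <- mg$ratio.x - mg$ratio.y
      if (nrow(mg) < 2 || stats::sd(diffs) == 0) {
        return(data.frame(mult_a = m1, mult_b = m2, n = nrow(mg),
                          t = NA_real_, p = NA_real_, degenerate = TRUE))
      }
      tt <- stats::t.test(mg$ratio.x, mg$ratio.y, paired = TRUE)
      data.frame(mult_a = m1, mult_b = m2, n = nrow(mg),
                 t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
    }))
    pw$p_holm <- NA_real_
    ok <- !pw$degenerate
    pw$p_holm[ok] <- stats::p.adjust(pw$p[ok], method = "holm")
  }
  list(per_multiplier = per, pairwise = pw)
}
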