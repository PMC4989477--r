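# FFT spectra, resting alpha, peak ratios, entrainment classification,
# ratio statistics.

make_block <- function(data, sfreq = 250, layout = tiny_layout(2),
                       f_stim = 10, n_flash = 40) {
  period <- round(sfreq / f_stim)
  structure(list(data = data, sfreq = sfreq, multiplier = 1,
                 stim_freq_hz = f_stim,
                 flash_onsets = 1L + (0:(n_flash - 1)) * period,
                 period_samples = period, baseline_samples = 0L,
                 n_trains_averaged = 1L, layout = layout, meta = list()),
            class = "averaged_block")
}

test_that("amplitude convention: unit sine has amplitude one; subset mean is linear", {
  sfreq <- 256
  n <- 1024                     # integer cycles of 8 Hz
  t <- (0:(n - 1)) / sfreq
  x <- sin(2 * pi * 8 * t)
  sp <- amplitude_spectrum(x, sfreq)
  expect_equal(sp$amplitude[which.min(abs(sp$freqs - 8))], 1, tolerance = 1e-6)
  expect_equal(sp$freqs[which.max(sp$amplitude)], 8, tolerance = sp$resolution_hz)
  expect_equal(sp$power, sp$amplitude^2)
  expect_true(all(diff(sp$freqs) > 0))
  # two channels with amplitudes 1 and 3 -> subset mean 2
  sp2 <- amplitude_spectrum(rbind(x, 3 * x), sfreq)
  expect_equal(max(sp2$amplitude), 2, tolerance = 1e-6)
})

test_that("Parseval consistency holds under the documented normalization", {
  sfreq <- 200
  set.seed(21)
  x <- rnorm(300)
  x <- x - mean(x)
  sp <- amplitude_spectrum(x, sfreq)
  # sum over one-sided bins (DC/Nyquist excluded) of amp^2 equals
  # 2 * nfft * energy / n^2 under the 2|X|/n convention
  inner <- 2:(length(sp$amplitude) - 1)
  lhs <- sum(sp$amplitude[inner]^2)
  rhs <- 2 * sp$n_fft * sum(x^2) / sp$n_window^2
  expect_equal(lhs, rhs, tolerance = 0.02)
})

test_that("white-noise spectrum is flat within sampling error", {
  sfreq <- 250
  set.seed(31)
  bandmeans <- replicate(30, {
    x <- matrix(rnorm(8 * 2048), 8)
    sp <- amplitude_spectrum(x, sfreq)
    lo <- sp$amplitude[sp$freqs >= 10 & sp$freqs < 40]
    hi <- sp$amplitude[sp$freqs >= 60 & sp$freqs < 90]
    mean(lo) / mean(hi)
  })
  expect_equal(mean(bandmeans), 1, tolerance = 0.03)
})

test_that("compute_spectrum rejects mixed-type subsets and uses the stimulus window", {
  lay <- tiny_layout(2)
  data <- matrix(sin(2 * pi * 10 * (0:1199) / 250), nrow(lay), 1200,
                 byrow = TRUE)
  blk <- make_block(data, layout = lay)
  expect_error(compute_spectrum(blk, subset = lay$name[c(1, 3)]), "mix")
  sp <- compute_spectrum(blk)
  expect_equal(sp$freqs[which.max(sp$amplitude)], 10, tolerance = 0.15)
  expect_length(sp$channel_subset, length(occipital_gradiometers(lay)))
})

test_that("resting alpha estimation finds the peak and flags featureless spectra", {
  proto <- tiny_protocol()
  lay <- tiny_layout()
  # wander-free oscillator so the peak sits exactly at alpha
  par <- noiseless_params(seed = 8, alpha_wander_hz = 0)
  rest <- simulate_rest(proto, lay, par)
  est <- estimate_resting_alpha(rest)
  expect_true(est$detected)
  expect_equal(est$alpha_hz, 10.58, tolerance = 0.05)
  # argmax picks the larger of two peaks
  sfreq <- 250
  t <- (0:(sfreq * 20 - 1)) / sfreq
  two <- sin(2 * pi * 8 * t) + 2 * sin(2 * pi * 11 * t)
  rec2 <- rest
  rec2$data <- matrix(rep(two, nrow(lay)), nrow(lay), byrow = TRUE)
  rec2$sfreq <- sfreq
  expect_equal(estimate_resting_alpha(rec2)$alpha_hz, 11, tolerance = 0.05)
  # pure noise -> flagged, not extrapolated (24-channel occipital subset
  # as in the full layout; few-channel averages fluctuate too much to
  # separate peak from floor)
  set.seed(4)
  full <- meg_layout()
  rec3 <- structure(list(data = matrix(rnorm(nrow(full) * 5000), nrow(full)),
                         sfreq = sfreq, layout = full,
                         events = NULL, meta = list()),
                    class = "meg_recording")
  expect_false(estimate_resting_alpha(rec3)$detected)
  expect_error(estimate_resting_alpha(structure(
    list(data = matrix(0, nrow(lay), 100), sfreq = 250, layout = lay,
         events = NULL, meta = list()), class = "meg_recording")), "10 s")
})

test_that("alpha peak ratio is 1 for identical spectra and scales linearly", {
  sfreq <- 250
  t <- (0:2047) / sfreq
  x <- sin(2 * pi * 10 * t)
  sp <- amplitude_spectrum(x, sfreq)
  sp2 <- amplitude_spectrum(2 * x, sfreq)
  expect_equal(alpha_peak_ratio(sp, sp, 10)$ratio, 1)
  expect_equal(alpha_peak_ratio(sp2, sp, 10)$ratio, 2, tolerance = 1e-9)
  zero <- amplitude_spectrum(0 * x, sfreq)
  expect_error(alpha_peak_ratio(sp, zero, 10), "zero")
  short <- amplitude_spectrum(x[1:1000], sfreq)
  expect_error(alpha_peak_ratio(short, sp, 10), "resolution")
  expect_silent(alpha_peak_ratio(short, sp, 10, check_resolution = FALSE))
})

test_that("entrainment classifier applies both rules with a trace", {
  sfreq <- 250
  t <- (0:2047) / sfreq
  sp <- amplitude_spectrum(sin(2 * pi * 10 * t), sfreq)
  r1 <- classify_entrainment(sp, 10, cohort_max_amp = 2)
  expect_true(r1$entrained)
  expect_true(r1$rule_trace$freq_match && r1$rule_trace$amp_above)
  expect_equal(r1$response_freq_hz, 10, tolerance = sp$raw_resolution_hz)
  # amplitude rule: peak at 10% of the cohort max fails
  r2 <- classify_entrainment(sp, 10, cohort_max_amp = 10)
  expect_false(r2$entrained)
  expect_true(r2$rule_trace$freq_match)
  expect_false(r2$rule_trace$amp_above)
  # frequency rule: stimulating at 9.5 Hz while the response sits at 10
  r3 <- classify_entrainment(sp, 9.5, cohort_max_amp = 2)
  expect_false(r3$entrained)
  expect_false(r3$rule_trace$freq_match)
  expect_error(classify_entrainment(sp, 1, cohort_max_amp = 2), "outside")
})

test_that("ratio statistics match hand-computed t quantities", {
  ratios <- data.frame(
    subject = rep(1:5, times = 2),
    multiplier = rep(c(0.5, 2.0), each = 5),
    ratio = c(1.4, 1.2, 1.6, 1.1, 1.3, 0.6, 0.8, 0.5, 0.7, 0.9))
  out <- test_ratios(ratios)
  x <- ratios$ratio[1:5]
  t_hand <- (mean(x) - 1) / (stats::sd(x) / sqrt(5))
  row <- out$per_multiplier[out$per_multiplier$multiplier == 0.5, ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$p_greater, stats::pt(t_hand, 4, lower.tail = FALSE))
  expect_equal(row$p_greater + row$p_less, 1)
  # paired test equals the hand formula on the differences
  d <- ratios$ratio[1:5] - ratios$ratio[6:10]
  t_pair <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(out$pairwise$t[1], t_pair, tolerance = 1e-12)
  # degenerate: identical ratios flag instead of erroring
  same <- data.frame(subject = 1:3, multiplier = 1, ratio = c(1, 1, 1))
  out2 <- test_ratios(same, pairwise = FALSE)
  expect_true(out2$per_multiplier$degenerate)
})
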