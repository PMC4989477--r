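# Topographic Matching Pursuit: dictionary, multichannel atom fitting,
# reference atom, correlation sequences.

test_that("dictionary atoms are grid-complete with unit-norm envelopes", {
  d <- build_gabor_dictionary(125, 1000)
  # atom count = |scales| x sum of per-scale translations x |modulations|
  n_trans <- sum(vapply(d$scales, function(s) {
    length(unique(round(seq(1, 125, by = max(1, round(s / 4))))))
  }, 0L))
  expect_equal(nrow(d$params), n_trans * length(d$freqs_hz))
  # unit l2 norm of every envelope
  norms <- sqrt(colSums(Mod(d$atoms)^2))
  expect_true(all(abs(norms - 1) < 1e-12))
  # modulation grid covers 10 Hz within one step
  expect_lt(min(abs(d$freqs_hz - 10)), d$freq_step_hz + 1e-12)
  expect_true(min(d$freqs_hz) <= 2 && max(d$freqs_hz) <= 30)
  expect_error(build_gabor_dictionary(4, 1000), "short")
})

test_that("fit_atom recovers planted dictionary atoms exactly", {
  d <- build_gabor_dictionary(50, 250)
  g <- photodrive:::gabor_atom_waveform(50, 16, 25, 2 * pi * 10 / 250)
  env <- Mod(g)
  t_idx <- 1:50
  make_ch <- function(amp, ph) amp * env * cos(2 * pi * 10 / 250 * (t_idx - 25) + ph)
  X <- rbind(make_ch(3, 0.7), make_ch(1.5, -0.3))
  a <- fit_atom(X, d)
  expect_equal(c(a$s, a$u), c(16, 25))
  expect_equal(a$xi, 2 * pi * 10 / 250, tolerance = 1e-12)
  expect_equal(a$amps, c(3, 1.5), tolerance = 1e-6)
  expect_equal(a$phases, c(0.7, -0.3), tolerance = 1e-6)
  # amplitude ratio is preserved under scaling (linearity)
  a2 <- fit_atom(rbind(make_ch(2, 0.2), make_ch(1, 0.2)), d)
  expect_equal(a2$amps[1] / a2$amps[2], 2, tolerance = 1e-6)
  # all-zero window flags degenerate
  a0 <- fit_atom(matrix(0, 3, 50), d)
  expect_true(a0$degenerate)
  expect_equal(a0$amps, rep(0, 3))
  expect_error(fit_atom(matrix(NA_real_, 1, 50), d), "finite")
})

test_that("fit_atom agrees with the exhaustive projection oracle", {
  d <- build_gabor_dictionary(32, 250, freq_step_hz = 2)
  set.seed(17)
  for (i in 1:12) {
    X <- matrix(rnorm(4 * 32), 4)
    a <- fit_atom(X, d)
    o <- oracle_fit_atom(X, d)
    expect_equal(c(a$s, a$u, a$xi), c(o$s, o$u, o$xi),
                 label = sprintf("trial %d params", i))
    expect_equal(a$criterion, o$crit, tolerance = 1e-9)
    # Bessel-type bound: captured energy cannot exceed signal energy
    expect_lte(a$criterion, sum(X^2) * (1 + 1e-12))
  }
})

test_that("planted-atom modulation is recovered within one grid step under noise", {
  d <- build_gabor_dictionary(40, 250)
  set.seed(23)
  hits <- replicate(60, {
    f0 <- sample(seq(6, 20, by = 0.5), 1)
    g <- photodrive:::gabor_atom_waveform(40, 16, 17, 2 * pi * f0 / 250)
    sig <- Re(g * exp(1i * runif(1, -pi, pi)))
    snr <- 3
    noise_sd <- stats::sd(sig) / snr
    X <- rbind(sig + rnorm(40, 0, noise_sd), sig + rnorm(40, 0, noise_sd))
    a <- fit_atom(X, d)
    abs(a$xi - 2 * pi * f0 / 250) <= 2 * pi * d$freq_step_hz / 250 + 1e-12
  })
  expect_gte(mean(hits), 0.95)
})

test_that("atom sequences have 40 + 10 entries with stable modulation on stationary input", {
  proto <- tiny_protocol(trains = 3)
  lay <- tiny_layout(3)
  rec <- simulate_block(1.00, proto, lay, noiseless_params(seed = 12))
  blk <- run_preproc(rec, proto)
  atoms <- atom_sequence(blk)
  expect_length(atoms, 50)
  # insufficient post-stimulation data is rejected
  short <- blk
  short$data <- short$data[, 1:(short$flash_onsets[40] + short$period_samples), drop = FALSE]
  expect_error(atom_sequence(short), "post-stimulation")
  # a strictly stationary sinusoidal block with multi-cycle analysis
  # windows: all 50 atoms share the modulation within one grid step
  # (below about one carrier cycle per envelope the modulation of a
  # Gabor atom is not identifiable, so the window must hold several
  # cycles for this stability property to be well-posed)
  sfreq <- 250; L <- 120
  n <- 500 + 51 * L
  tt <- seq_len(n) / sfreq
  stat_blk <- structure(list(
    data = matrix(rep(sin(2 * pi * 10 * tt), nrow(lay)), nrow(lay), byrow = TRUE),
    sfreq = sfreq, multiplier = 0.2, stim_freq_hz = sfreq / L,
    flash_onsets = as.integer(200 + (0:39) * L), period_samples = L,
    baseline_samples = 125L, n_trains_averaged = 1L, layout = lay,
    meta = list()), class = "averaged_block")
  atoms2 <- atom_sequence(stat_blk)
  xi <- vapply(atoms2, `[[`, 0, "xi")
  d_step <- 2 * pi * 0.5 / sfreq
  expect_lt(max(xi) - min(xi), d_step + 1e-12)
})

test_that("reference atom averages parameters, amplitudes and phases circularly", {
  mk <- function(s, u, xi, amps, phases) {
    photodrive:::new_tmp_atom(s, u, xi, amps, phases)
  }
  a1 <- mk(8, 10, 0.2, c(1, 2), c(pi - 0.1, 0.3))
  a2 <- mk(16, 14, 0.3, c(3, 2), c(-pi + 0.1, 0.5))
  ref <- reference_atom(list(a1, a2))
  expect_equal(ref$s, 12)
  expect_equal(ref$u, 12)
  expect_equal(ref$xi, 0.25)
  expect_equal(ref$amps, c(2, 2))
  # circular mean of {pi-0.1, -pi+0.1} is pi, not 0
  resultant <- (exp(1i * (pi - 0.1)) + exp(1i * (-pi + 0.1))) / 2
  expect_equal(abs(ref$phases[1]), pi, tolerance = 1e-9)
  expect_equal(ref$phases[2], Arg(exp(1i * 0.3) + exp(1i * 0.5)),
               tolerance = 1e-12)
  expect_equal(Mod(resultant), cos(0.1), tolerance = 1e-12)
  expect_error(reference_atom(list()), "empty")
  # identical atoms average to themselves
  same <- reference_atom(list(a1, a1, a1))
  expect_equal(same$amps, a1$amps)
  expect_equal(same$phases, a1$phases, tolerance = 1e-12)
})

test_that("correlation sequences are lag-max normalized correlations in [0, 1]", {
  mk <- function(s, u, xi, amps, phases) {
    photodrive:::new_tmp_atom(s, u, xi, amps, phases)
  }
  L <- 48
  ref <- mk(24, 24, 2 * pi * 10 / 250, c(1, 2), c(0, 1))
  # identical atom -> coefficient 1 on every channel
  cs <- correlation_sequence(ref, list(ref), L)
  expect_equal(unname(cs$coefficients[, 1]), c(1, 1), tolerance = 1e-9)
  # time-shifted copy -> lag-max absorbs the shift
  shifted <- mk(24, 29, 2 * pi * 10 / 250, c(1, 2), c(0, 1))
  cs2 <- correlation_sequence(ref, list(shifted), L)
  expect_gt(min(cs2$coefficients[, 1]), 0.97)
  # far-off modulation (2 vs 10 Hz over a half-second window) -> low
  L2 <- 125
  far <- mk(100, 63, 2 * pi * 2 / 250, c(1, 1), c(0, 0))
  ref_n <- mk(100, 63, 2 * pi * 10 / 250, c(1, 1), c(0, 0))
  cs3 <- correlation_sequence(ref_n, list(far), L2)
  expect_lt(max(cs3$coefficients[, 1]), 0.3)
  # zero-energy channel -> coefficient 0
  dead <- mk(24, 24, 2 * pi * 10 / 250, c(0, 1), c(0, 0))
  cs4 <- correlation_sequence(ref, list(dead), L)
  expect_equal(cs4$coefficients[1, 1], 0)
  # matches the brute-force lag search
  w_ref <- photodrive:::atom_waveform_real(ref_n, 2, L2)
  w_far <- photodrive:::atom_waveform_real(far, 2, L2)
  expect_equal(cs3$coefficients[2, 1], oracle_xcorr_max(w_far, w_ref),
               tolerance = 1e-9)
  expect_equal(cs2$coefficients[2, 1],
               oracle_xcorr_max(photodrive:::atom_waveform_real(shifted, 2, L),
                                photodrive:::atom_waveform_real(ref, 2, L)),
               tolerance = 1e-9)
})

test_that("correlation coefficients stay in [0, 1] for random atoms (fuzz)", {
  set.seed(29)
  L <- 30
  for (i in 1:40) {
    mk <- function() photodrive:::new_tmp_atom(
      s = sample(c(4, 8, 16, 32), 1), u = sample(1:L, 1),
      xi = runif(1, 0.05, pi * 0.8),
      amps = abs(rnorm(3)), phases = runif(3, -pi, pi))
    cs <- correlation_sequence(mk(), list(mk(), mk()), L)
    expect_true(all(cs$coefficients >= 0 & cs$coefficients <= 1))
  }
})

test_that("atom tables round-trip the shared and per-channel parameters", {
  a <- photodrive:::new_tmp_atom(8, 5, 0.3, c(1.5, 2.5), c(0.1, -0.2),
                                 criterion = 3, channel_names = c("A", "B"))
  df <- atoms_to_df(list(a, a), subject = 1, multiplier = 1.0)
  expect_equal(nrow(df), 2)
  expect_equal(df$s, c(8, 8))
  expect_equal(df$amp_A, c(1.5, 1.5))
  expect_equal(df$phase_B, c(-0.2, -0.2))
})
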