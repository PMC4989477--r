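# Synthetic-session generator: protocol, layout, sources, projection,
# determinism and ground-truth consistency.

test_that("protocol carries the canonical multipliers and randomizes order by seed", {
  expect_length(default_multipliers(), 20)
  p1 <- generate_protocol(10.0, seed = 1)
  p2 <- generate_protocol(10.0, seed = 1)
  p3 <- generate_protocol(10.0, seed = 2)
  expect_setequal(p1$multipliers, default_multipliers())
  expect_identical(p1$multipliers, p2$multipliers)
  expect_false(identical(p1$multipliers, p3$multipliers))
  expect_identical(p1$trains_per_block, 30L)
  expect_identical(p1$flashes_per_train, 40L)
  expect_equal(p1$inter_train_rest_s, 4)
  expect_equal(p1$sfreq_hz, 1000)
  expect_error(generate_protocol(5, seed = 1), "alpha")
  # stimulation frequencies for a 10.58 Hz alpha span the rod range
  f <- stim_frequencies(stim_protocol(10.58))
  expect_equal(unname(range(f)), c(4.232, 24.334), tolerance = 1e-12)
})

test_that("default layout has 102 triplets, 306 channels and 24 occipital gradiometers", {
  lay <- meg_layout()
  expect_equal(nrow(lay), 306)
  expect_equal(length(unique(lay$triplet)), 102)
  counts <- table(lay$type)
  expect_equal(unname(counts[c("mag", "grad")]), c(102L, 204L),
               ignore_attr = TRUE)
  per_triplet <- table(lay$triplet, lay$type)
  expect_true(all(per_triplet[, "mag"] == 1 & per_triplet[, "grad"] == 2))
  expect_length(occipital_gradiometers(lay), 24)
  # occipital sites are the most posterior ones
  expect_lt(max(lay$y[lay$region == "occipital"]), 0)
})

test_that("source phenomenology matches the ground-truth labels", {
  proto <- tiny_protocol(trains = 4)
  par <- noiseless_params(seed = 2)
  spec_peak <- function(m) {
    src <- simulate_source(m, proto, par, n_trains = 4)
    i <- which(src$t >= src$train_onsets[2], arr.ind = TRUE)
    x <- src$x[i]
    n <- length(x)
    a <- Mod(stats::fft(x))[1:(n %/% 2)]
    (which.max(a) - 1) * proto$sfreq_hz / n
  }
  # locked at the stimulation frequency inside the band, including 0.95
  expect_equal(spec_peak(1.00), 10.58, tolerance = 0.15)
  expect_equal(spec_peak(0.95), 0.95 * 10.58, tolerance = 0.15)
  # fused: no sustained oscillation at 2*alpha; residual alpha remains
  src2 <- simulate_source(2.00, proto, par, n_trains = 4)
  i <- which(src2$t >= src2$train_onsets[2] & src2$t < src2$train_ends[2])
  a2 <- Mod(stats::fft(src2$x[i]))
  fr <- (seq_along(a2) - 1) * proto$sfreq_hz / length(a2)
  amp_at <- function(a, fr, f0) max(a[abs(fr - f0) < 0.8])
  src1 <- simulate_source(1.00, proto, par, n_trains = 4)
  i1 <- which(src1$t >= src1$train_onsets[2] & src1$t < src1$train_ends[2])
  a1 <- Mod(stats::fft(src1$x[i1]))
  fr1 <- (seq_along(a1) - 1) * proto$sfreq_hz / length(a1)
  expect_lt(amp_at(a2, fr, 2 * 10.58) / amp_at(a1, fr1, 10.58), 0.2)
  # transient bump present ~200 ms after train onset in fused blocks
  t_on <- src2$train_onsets[2] + 0.2
  i_bump <- which(abs(src2$t - t_on) < 0.05)
  i_pre <- which(src2$t > src2$train_onsets[2] - 0.45 &
                   src2$t < src2$train_onsets[2] - 0.35)
  expect_gt(max(abs(src2$x[i_bump])), 3 * max(abs(src2$x[i_pre])))
  expect_true(src2$truth$fused)
  expect_false(src2$truth$entrained)
  expect_true(src1$truth$entrained)
})

test_that("sessions embed the protocol event structure and are seed-deterministic", {
  proto <- tiny_protocol(trains = 3)
  proto$multipliers <- c(1.00, 2.00)
  lay <- tiny_layout()
  par <- noiseless_params(seed = 5)
  s1 <- simulate_session(proto, lay, par)
  expect_length(s1$blocks, 2)
  b <- s1$blocks[["1.00"]]
  expect_equal(sum(b$events$code == 1), 3 * 40)
  expect_equal(sum(b$events$code == 2), 3)
  expect_true(all(b$events$sample >= 1 & b$events$sample <= ncol(b$data)))
  expect_equal(nrow(s1$ground_truth), 2)
  expect_true(s1$ground_truth$entrained[s1$ground_truth$multiplier == 1.00])
  expect_true(s1$ground_truth$fused[s1$ground_truth$multiplier == 2.00])
  # bit-identical under the same seed
  s2 <- simulate_session(proto, lay, par)
  expect_identical(s1$blocks[["2.00"]]$data, s2$blocks[["2.00"]]$data)
  expect_identical(s1$rest$data, s2$rest$data)
  # 20 blocks with the full default multiplier set
  proto20 <- tiny_protocol(trains = 1)
  s20 <- simulate_session(proto20, lay, par)
  expect_length(s20$blocks, 20)
})

test_that("noiseless projection is exactly rank-2 and scales linearly with gain", {
  proto <- tiny_protocol(trains = 2)
  lay <- tiny_layout()
  par <- noiseless_params(seed = 3)
  rec <- simulate_block(1.00, proto, lay, par)
  # residuals after projecting out the two source topographies vanish
  W <- cbind(photodrive:::posterior_topography(lay),
             photodrive:::anterior_topography(lay))
  resid <- rec$data - W %*% qr.solve(W, rec$data)
  expect_lt(max(abs(resid)), 1e-8 * max(abs(rec$data)))
  # doubling the resonance gain doubles the occipital plateau amplitude
  g <- resonance_gain(1.00, par)
  par2 <- noiseless_params(seed = 3,
                           resonance_gains = stats::setNames(2 * g, "1.00"))
  rec2 <- simulate_block(1.00, proto, lay, par2)
  occ <- occipital_gradiometers(lay)[1]
  src <- simulate_source(1.00, proto, par, n_trains = 2)
  plateau <- which(src$t > src$train_onsets[1] + 1.5 &
                     src$t < src$train_ends[1])
  r <- stats::sd(rec2$data[occ, plateau]) / stats::sd(rec$data[occ, plateau])
  expect_equal(r, 2, tolerance = 0.02)
})

test_that("averaged-block fast path attenuates incoherent parts and keeps coherent ones", {
  proto <- tiny_protocol(trains = 9)
  lay <- tiny_layout()
  par <- noiseless_params(seed = 4)
  fast <- simulate_averaged_block(2.00, proto, lay, par)
  expect_equal(fast$meta$represents_average_of, 9L)
  expect_equal(sum(fast$events$code == 1), 40)
  src_full <- simulate_source(2.00, proto, par, n_trains = 1, incoherent_scale = 1)
  src_fast <- simulate_source(2.00, proto, par, n_trains = 1,
                              incoherent_scale = 1 / sqrt(9))
  # the transient (coherent) is unscaled; rest-segment alpha shrinks by 3
  i_rest <- which(src_full$t < 0.8)
  expect_equal(stats::sd(src_fast$x[i_rest]) / stats::sd(src_full$x[i_rest]),
               1 / 3, tolerance = 0.01)
  t_on <- src_full$train_onsets[1] + 0.2
  i_bump <- which.min(abs(src_full$t - t_on))
  expect_equal(src_fast$x[i_bump], src_full$x[i_bump], tolerance = 0.15)
})

test_that("session container round trip preserves data bit-exactly with a YAML sidecar", {
  proto <- tiny_protocol(trains = 2)
  proto$multipliers <- c(1.00)
  lay <- tiny_layout(4)
  sess <- simulate_session(proto, lay, response_model_params(snr = 2, seed = 9))
  path <- tempfile(fileext = ".rds")
  write_session(sess, path)
  back <- read_session(path)
  expect_identical(back$blocks[["1.00"]]$data, sess$blocks[["1.00"]]$data)
  expect_identical(back$rest$data, sess$rest$data)
  sidecar <- sub("\\.rds$", ".yaml", path)
  expect_true(file.exists(sidecar))
  meta <- yaml::read_yaml(sidecar)
  expect_equal(meta$protocol$alpha_hz, proto$alpha_hz)
  expect_equal(meta$n_channels, nrow(lay))
  unlink(c(path, sidecar))
})
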