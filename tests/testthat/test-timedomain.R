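# MGFP, Hilbert envelope, on/off transient detection, group test.

test_that("mgfp equals the direct spatial RMS formula", {
  lay <- tiny_layout(2)
  n_mag <- sum(lay$type == "mag")
  data <- matrix(0, nrow(lay), 10)
  data[lay$type == "mag", ] <- c(3, 4)[seq_len(n_mag) %% 2 + 1]
  blk <- structure(list(data = data, layout = lay, sfreq = 100),
                   class = "averaged_block")
  expect_equal(unique(round(mgfp(blk, "mag"), 12)), sqrt((9 + 16) / 2))
  # all channels equal to a -> |a| everywhere; homogeneity of degree 1
  data2 <- matrix(-2, nrow(lay), 5)
  blk$data <- data2
  expect_equal(mgfp(blk, "mag"), rep(2, 5))
  blk$data <- 3 * data2
  expect_equal(mgfp(blk, "mag"), rep(6, 5))
  blk$layout <- lay[lay$type == "grad", ]
  blk$data <- data2[lay$type == "grad", ]
  expect_error(mgfp(blk, "mag"), "type")
})

test_that("Hilbert envelope recovers unit and modulated amplitudes", {
  sfreq <- 250
  t <- (0:(8 * sfreq - 1)) / sfreq
  lay <- tiny_layout(2)
  mk_blk <- function(x) structure(
    list(data = matrix(rep(x, nrow(lay)), nrow(lay), byrow = TRUE),
         sfreq = sfreq, layout = lay),
    class = "averaged_block")
  interior <- seq(sfreq, length(t) - sfreq)
  # unit sinusoid -> envelope 1 (unstandardized to keep units)
  env1 <- envelope(mk_blk(sin(2 * pi * 10 * t)), standardize = FALSE)
  expect_equal(max(abs(env1$envelope[interior] - 1)), 0, tolerance = 0.01)
  # envelope never falls below |signal| (beyond numerical tolerance)
  expect_true(all(env1$envelope[interior] + 1e-6 >=
                    abs(sin(2 * pi * 10 * t))[interior]))
  # slow amplitude modulation is recovered
  a <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  env2 <- envelope(mk_blk(a * sin(2 * pi * 10 * t)), standardize = FALSE)
  expect_equal(env2$envelope[interior], a[interior], tolerance = 0.02)
  # zero signal -> zero envelope
  env0 <- envelope(mk_blk(0 * t), standardize = FALSE)
  expect_equal(max(env0$envelope), 0)
  expect_error(envelope(mk_blk(t), window = seq_len(length(t) + 5)), "window")
})

test_that("first qualifying envelope peak defines the transient and its latency", {
  sfreq <- 1000
  n <- 6000
  t <- (seq_len(n) - 1) / sfreq
  onset <- 1001L
  endst <- 3001L
  # smooth low-level ripple: stays below the mean + 3 SD threshold
  base <- 1 + 0.01 * sin(2 * pi * 3 * t)
  bump <- function(at_ms, amp, ref) amp * exp(-((t - (ref - 1) / sfreq -
    at_ms / 1000) / 0.02)^2)
  # single planted on-bump at +200 ms
  env <- base + bump(200, 2, onset) + bump(150, 2, endst)
  det <- detect_on_off(env, onset, endst, sfreq = sfreq)
  expect_true(det$on$detected && det$off$detected)
  expect_equal(det$on$latency_ms, 200, tolerance = 2)
  expect_equal(det$off$latency_ms, 150, tolerance = 2)
  expect_gt(det$on$latency_ms, 0)
  # two bumps: the first one wins
  env2 <- base + bump(150, 2, onset) + bump(400, 2, onset)
  det2 <- detect_on_off(env2, onset, endst, sfreq = sfreq)
  expect_equal(det2$on$latency_ms, 150, tolerance = 2)
  # sub-threshold envelope -> not detected
  det3 <- detect_on_off(base, onset, endst, sfreq = sfreq)
  expect_false(det3$on$detected)
  expect_false(det3$off$detected)
  expect_true(is.na(det3$on$latency_ms))
})

test_that("off-occurrence group test matches hand-computed paired statistics", {
  # 8 subjects, all-off at high frequencies, none at low -> one-sided
  # paired t on differences of 1 with zero variance is degenerate-free
  # only with jitter; plant a small asymmetry instead
  resp <- expand.grid(subject = 1:8,
                      multiplier = c(0.4, 0.8, 1.0, 1.3, 2.0, 2.3))
  resp$off_detected <- resp$multiplier >= 1.3
  resp$off_detected[resp$subject == 1 & resp$multiplier == 0.4] <- TRUE
  out <- test_off_occurrence(resp)
  d <- out$per_subject$prop_high - out$per_subject$prop_low
  t_hand <- mean(d) / (stats::sd(d) / sqrt(8))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, stats::pt(t_hand, 7, lower.tail = FALSE))
  expect_lt(out$p, 0.05)
  # identical occurrence in both groups -> t = 0, degenerate flag
  resp2 <- resp
  resp2$off_detected <- TRUE
  out2 <- test_off_occurrence(resp2)
  expect_true(out2$degenerate)
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  # ANOVA table appears when on-response parameters are present
  resp$on_detected <- TRUE
  set.seed(67)
  resp$on_latency_ms <- rnorm(nrow(resp), 200, 18)
  resp$on_amplitude <- rnorm(nrow(resp), 2, 0.2)
  out3 <- test_off_occurrence(resp)
  expect_false(is.null(out3$anova_on))
  ftab <- out3$anova_on$latency[[1]]
  expect_equal(ftab$Df[1], length(unique(resp$multiplier)) - 1)
})
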