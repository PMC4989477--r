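# Synthetic session generator: a phase-oscillator source model projected
# through fixed dipolar topographies onto an idealized whole-head layout.

#' Simulate the posterior source of one stimulation block
#'
#' Produces the noiseless source time courses of a single frequency
#' block: the posterior source (free-running alpha, stimulus-locked
#' driven oscillation and, for fused multipliers, on/off transients) and
#' the incoherent anterior background oscillator, together with the
#' event times and ground-truth labels.
#'
#' Inside the entrainment band the driven component oscillates at the
#' stimulation frequency with the resonance-gain amplitude, ramps up
#' over the engagement periods, persists for the drawn number of
#' preservation periods after the last flash and then decays. At or
#' above the fusion threshold no oscillation is driven; a transient
#' Gabor bump appears `on_latency_ms` after train onset and a smaller
#' one after the end of the last flash period, while the free alpha is
#' partially suppressed. Free alpha at `alpha_hz` is present during all
#' rest periods.
#'
#' @param multiplier Stimulation-frequency multiplier.
#' @param protocol A [stim_protocol()].
#' @param params A [response_model_params()].
#' @param n_trains Number of trains to simulate (defaults to the
#'   protocol's `trains_per_block`).
#' @param incoherent_scale Amplitude factor applied to the incoherent
#'   (non-stimulus-locked) components; used by the averaged-block fast
#'   path.
#' @param block_seed Integer seed for the block's random elements
#'   (wander phases, preservation draw).
#' @return List with elements `t` (seconds), `x` (posterior source),
#'   `background` (anterior source), `flash_times`, `train_onsets`,
#'   `train_ends` (seconds), `stim_freq_hz`, and `truth`.
#' @export
simulate_source <- function(multiplier, protocol, params,
                            n_trains = protocol$trains_per_block,
                            incoherent_scale = 1,
                            block_seed = derive_seed(params$seed, round(multiplier * 100))) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(params, "response_model_params"),
            multiplier > 0)
  sf <- protocol$sfreq_hz
  f <- protocol$alpha_hz * multiplier
  n_flash <- protocol$flashes_per_train
  t_train <- n_flash / f
  rest <- protocol$inter_train_rest_s
  lead_in <- 1.0
  dur <- lead_in + n_trains * (t_train + rest)
  n <- round(dur * sf)
  t <- (seq_len(n) - 1) / sf

  truth <- ground_truth_labels(multiplier, params)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(block_seed)
  phases <- runif(6, 0, 2 * pi)
  n_pres <- if (truth$entrained) {
    vals <- seq(params$preservation_periods[1], params$preservation_periods[2])
    vals[sample.int(length(vals), 1)]
  } else 0L

  train_onsets <- lead_in + (seq_len(n_trains) - 1) * (t_train + rest)
  train_ends <- train_onsets + t_train           # end of last flash period
  flash_times <- as.vector(outer((seq_len(n_flash) - 1) / f, train_onsets, `+`))
  flash_times <- sort(flash_times)

  # --- free-running alpha: slowly wandering frequency, amplitude shaped
  # by the stimulation state -------------------------------------------
  f_alpha <- protocol$alpha_hz +
    params$alpha_wander_hz * sin(2 * pi * t / 11.3 + phases[1])
  phi_alpha <- 2 * pi * cumsum(f_alpha) / sf + phases[2]
  a_env <- rep(1, n)
  recover_s <- params$alpha_recovery_s
  driven <- numeric(n)

  for (k in seq_len(n_trains)) {
    ts <- train_onsets[k]
    te <- train_ends[k]
    i_tr <- which(t >= ts & t < te)
    tau <- (t[i_tr] - ts) * f                    # time since onset, periods
    if (truth$entrained) {
      # recruitment of the free rhythm into the locked response is
      # immediate at train onset (phase capture, not amplitude decay)
      r <- pmin(1, (tau / params$engagement_periods)^2)
      a_env[i_tr] <- params$alpha_recruitment * (1 - r)
      # locked response: ramp, hold through preservation, then decay
      i_post <- which(t >= te & t < te + rest)
      tau_post <- (t[i_post] - te) * f
      env_post <- ifelse(tau_post <= n_pres, 1,
                         exp(-(tau_post - n_pres) / params$preservation_decay_periods))
      driven[i_tr] <- driven[i_tr] + truth$gain * r * cos(2 * pi * f * (t[i_tr] - ts))
      driven[i_post] <- driven[i_post] +
        truth$gain * env_post * cos(2 * pi * f * (t[i_post] - ts))
      # free alpha recovers during rest, after the driven decay
      i_rec <- which(t >= te & t < te + rest)
      rec <- pmin(1, pmax(0, (t[i_rec] - te - n_pres / f) / recover_s))
      a_env[i_rec] <- pmin(a_env[i_rec], params$alpha_recruitment + (1 - params$alpha_recruitment) * rec)
    } else if (truth$fused) {
      # perceptual desynchronization under fused flicker develops over
      # ~300 ms; an instantaneous amplitude step would ring through the
      # bandpass and plant spurious envelope peaks near the transients
      onset_ramp <- pmin(1, (t[i_tr] - ts) / 0.3)
      a_env[i_tr] <- 1 + (params$alpha_suppression - 1) * onset_ramp
      i_rec <- which(t >= te & t < te + rest)
      rec <- pmin(1, (t[i_rec] - te) / recover_s)
      a_env[i_rec] <- pmin(a_env[i_rec],
                           params$alpha_suppression + (1 - params$alpha_suppression) * rec)
      # coherent on-/off-transients
      driven <- driven +
        transient_bump(t, ts + params$on_latency_ms / 1000, params$on_amp, params) +
        transient_bump(t, te + params$off_latency_ms / 1000, params$off_amp, params)
    }
  }
  alpha_osc <- incoherent_scale * a_env * cos(phi_alpha)

  # --- anterior background oscillator (always on, never locked) --------
  f_bg <- params$background_freq_hz +
    params$background_freq_wander_hz * sin(2 * pi * t / 13.1 + phases[3])
  phi_bg <- 2 * pi * cumsum(f_bg) / sf + phases[4]
  a_bg <- params$background_amp *
    (1 + params$background_amp_wander * sin(2 * pi * t / 17.7 + phases[5]))
  background <- incoherent_scale * a_bg * cos(phi_bg)

  truth$n_preservation <- n_pres
  truth$on_latency_ms <- if (truth$fused) params$on_latency_ms else NA_real_
  truth$off_latency_ms <- if (truth$fused) params$off_latency_ms else NA_real_

  list(t = t, x = alpha_osc + driven, background = background,
       flash_times = flash_times, train_onsets = train_onsets,
       train_ends = train_ends, stim_freq_hz = f, truth = truth,
       lead_in_s = lead_in, n_trains = n_trains)
}

# Gaussian-windowed transient (Gabor bump) centred at t0 seconds.
#' @keywords internal
transient_bump <- function(t, t0, amp, params) {
  sigma <- params$transient_width_ms / 1000 / (2 * sqrt(2 * log(2)))
  out <- numeric(length(t))
  i <- which(abs(t - t0) < 5 * sigma)
  if (length(i)) {
    out[i] <- amp * exp(-(t[i] - t0)^2 / (2 * sigma^2)) *
      cos(2 * pi * params$transient_carrier_hz * (t[i] - t0))
  }
  out
}

#' Simulate the multichannel recording of one stimulation block
#'
#' Projects the block's posterior and anterior sources through fixed
#' dipolar topographies (magnetometers in fT, planar gradiometers in
#' fT/cm), adds independent Gaussian sensor noise at the `snr` scale and
#' embeds event markers for every flash and train boundary.
#'
#' @inheritParams simulate_source
#' @param layout A [meg_layout()].
#' @return A `meg_recording`.
#' @export
simulate_block <- function(multiplier, protocol, layout, params,
                           n_trains = protocol$trains_per_block,
                           incoherent_scale = 1,
                           block_seed = derive_seed(params$seed, round(multiplier * 100))) {
  stopifnot(inherits(layout, "meg_layout"))
  src <- simulate_source(multiplier, protocol, params,
                         n_trains = n_trains,
                         incoherent_scale = incoherent_scale,
                         block_seed = block_seed)
  w_post <- posterior_topography(layout)
  w_ant <- anterior_topography(layout)
  data <- w_post %o% src$x +
    w_ant %o% src$background
  data <- data + sensor_noise(layout, ncol(data), params,
                              scale = incoherent_scale,
                              noise_seed = derive_seed(block_seed, 17L))
  sf <- protocol$sfreq_hz
  events <- rbind(
    data.frame(sample = round(src$flash_times * sf) + 1L, code = 1L),
    data.frame(sample = round(src$train_onsets * sf) + 1L, code = 2L),
    data.frame(sample = round(src$train_ends * sf) + 1L, code = 3L)
  )
  events <- events[order(events$sample, events$code), ]
  rownames(events) <- NULL
  new_recording(data, sf, events, layout,
                meta = list(multiplier = multiplier,
                            stim_freq_hz = src$stim_freq_hz,
                            alpha_hz = protocol$alpha_hz,
                            truth = src$truth,
                            n_trains = src$n_trains,
                            represents_average_of = NA_integer_))
}

# Independent Gaussian sensor noise; SD per channel is the per-type RMS
# topography gain divided by snr (so snr is an amplitude SNR at a
# typical channel).
#' @keywords internal
sensor_noise <- function(layout, n_samples, params, scale = 1, noise_seed) {
  if (!is.finite(params$snr)) {
    return(matrix(0, nrow(layout), n_samples))
  }
  gains <- c(mag = 250, grad = 18)
  n_type <- as.numeric(table(layout$type)[names(gains)])
  sd_type <- gains / sqrt(n_type) / params$snr
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(noise_seed)
  noise <- matrix(stats::rnorm(nrow(layout) * n_samples), nrow(layout), n_samples)
  noise * as.numeric(scale * sd_type[layout$type])
}

#' @keywords internal
new_recording <- function(data, sfreq, events, layout, meta = list()) {
  stopifnot(is.matrix(data), nrow(data) == nrow(layout))
  if (nrow(events)) {
    stopifnot(all(events$sample >= 1), all(events$sample <= ncol(data)))
  }
  rownames(data) <- layout$name
  structure(list(data = data, sfreq = sfreq, events = events,
                 layout = layout, meta = meta),
            class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("MEG recording: %d channels x %d samples (%.1f s at %g Hz), %d events\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$sfreq, x$sfreq,
              nrow(x$events)))
  if (!is.null(x$meta$multiplier)) {
    cat(sprintf("  stimulation block: %.2f x alpha (%.2f Hz)\n",
                x$meta$multiplier, x$meta$stim_freq_hz))
  }
  invisible(x)
}

#' Simulate the resting-state segment
#'
#' Eyes-closed rest: free-running alpha plus the anterior background
#' oscillator and sensor noise; no events.
#'
#' @inheritParams simulate_block
#' @return A `meg_recording` of `resting_duration_s` seconds.
#' @export
simulate_rest <- function(protocol, layout, params,
                          block_seed = derive_seed(params$seed, 999L)) {
  sf <- protocol$sfreq_hz
  n <- round(protocol$resting_duration_s * sf)
  t <- (seq_len(n) - 1) / sf
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(block_seed)
  phases <- runif(6, 0, 2 * pi)
  f_alpha <- protocol$alpha_hz + params$alpha_wander_hz * sin(2 * pi * t / 11.3 + phases[1])
  x <- cos(2 * pi * cumsum(f_alpha) / sf + phases[2])
  f_bg <- params$background_freq_hz +
    params$background_freq_wander_hz * sin(2 * pi * t / 13.1 + phases[3])
  bg <- params$background_amp *
    (1 + params$background_amp_wander * sin(2 * pi * t / 17.7 + phases[5])) *
    cos(2 * pi * cumsum(f_bg) / sf + phases[4])
  data <- posterior_topography(layout) %o% x +
    anterior_topography(layout) %o% bg
  data <- data + sensor_noise(layout, n, params, noise_seed = derive_seed(block_seed, 17L))
  new_recording(data, sf, data.frame(sample = integer(0), code = integer(0)),
                layout, meta = list(segment = "rest", alpha_hz = protocol$alpha_hz))
}

#' Simulate a complete session
#'
#' Generates the resting segment and all frequency blocks of one
#' subject, in the protocol's presentation order, with ground-truth
#' labels for every downstream classifier. Latencies are jittered once
#' per subject (SD `latency_jitter_sd_ms`).
#'
#' @inheritParams simulate_block
#' @return A `photic_session`: list with `protocol`, `layout`, `params`,
#'   `rest` (a `meg_recording`), `blocks` (named list of
#'   `meg_recording`s keyed by formatted multiplier) and `ground_truth`
#'   (one row per block).
#' @export
simulate_session <- function(protocol, layout, params) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(layout, "meg_layout"),
            inherits(params, "response_model_params"))
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(params$seed, 555L))
  jit <- stats::rnorm(2, 0, params$latency_jitter_sd_ms)
  params$on_latency_ms <- max(50, params$on_latency_ms + jit[1])
  params$off_latency_ms <- max(30, params$off_latency_ms + jit[2])

  blocks <- list()
  truth <- list()
  for (m in protocol$multipliers) {
    key <- format_multiplier(m)
    blocks[[key]] <- simulate_block(m, protocol, layout, params)
    truth[[key]] <- blocks[[key]]$meta$truth
  }
  gt <- do.call(rbind, truth)
  rownames(gt) <- NULL
  structure(list(protocol = protocol, layout = layout, params = params,
                 rest = simulate_rest(protocol, layout, params),
                 blocks = blocks, ground_truth = gt),
            class = "photic_session")
}

#' Fast path: simulate a train-averaged block directly
#'
#' Returns a single-train recording in which the stimulus-locked
#' (coherent) components are exact and the incoherent components (free
#' alpha, background, sensor noise) are scaled by
#' `1/sqrt(trains_per_block)` -- the attenuation that train averaging
#' applies to them. For the linear preprocessing chain this is
#' distributionally equivalent to simulating and averaging all trains,
#' at a fraction of the cost. The recording's metadata marks the number
#' of trains it represents so that [epoch_and_average()] labels the
#' result correctly.
#'
#' @inheritParams simulate_block
#' @return A `meg_recording` containing one train.
#' @export
simulate_averaged_block <- function(multiplier, protocol, layout, params,
                                    block_seed = derive_seed(params$seed, round(multiplier * 100))) {
  rec <- simulate_block(multiplier, protocol, layout, params,
                        n_trains = 1L,
                        incoherent_scale = 1 / sqrt(protocol$trains_per_block),
                        block_seed = block_seed)
  rec$meta$represents_average_of <- protocol$trains_per_block
  rec
}

#' @export
print.photic_session <- function(x, ...) {
  cat(sprintf("Synthetic photic-driving session: alpha %.2f Hz, %d blocks, %d-channel layout\n",
              x$protocol$alpha_hz, length(x$blocks), nrow(x$layout)))
  print(x$ground_truth)
  invisible(x)
}
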