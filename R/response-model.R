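#' Response-model parameters for the synthetic generator
#'
#' Parameterizes the rod-driven response phenomenology emulated by the
#' generator: inside `entrainment_band` the posterior alpha oscillator
#' locks to the stimulation frequency with a multiplier-dependent
#' resonance gain; at and above `fusion_threshold_mult` the flicker is
#' perceived as fused (steady) light, so no oscillation is driven and
#' only transient on-/off-responses appear; in between the oscillator
#' free-runs at the individual alpha frequency.
#'
#' The generator additionally carries an incoherent anterior background
#' oscillator at a slowly wandering non-alpha frequency. Because the
#' driven response is stimulus-locked while alpha and background are
#' not, train averaging attenuates the latter by `1/sqrt(n_trains)`:
#' early stimulation periods of the averaged data are dominated by those
#' residuals, later ones by the locked response. This is what produces
#' the engagement/plateau/disengagement structure in the topographic
#' correlation sequences.
#'
#' @param entrainment_band Multiplier interval in which the oscillator
#'   locks to the stimulus (default `c(0.40, 1.10)`).
#' @param fusion_threshold_mult Multiplier at/above which flicker fuses
#'   (default 1.30).
#' @param resonance_gains Optional named numeric vector mapping
#'   multiplier (formatted `"%.2f"`) to amplitude gain. When `NULL`, a
#'   double-Gaussian profile peaking at 1.00 (gain 3.5) and 0.50
#'   (gain 2.5) over a base gain of 1.3 is used.
#' @param gain_base,gain_alpha,gain_alpha_width,gain_half,gain_half_width
#'   Parameters of the default resonance-gain profile.
#' @param resonance_gain_min Gain at/above which a block is labelled
#'   resonant in the ground truth (default 2).
#' @param on_latency_ms,off_latency_ms Transient latencies after train
#'   onset / end of the last flash period (defaults 200 and 150 ms).
#' @param latency_jitter_sd_ms Per-subject latency jitter SD (default 18).
#' @param transient_width_ms FWHM of the transient Gaussian envelope.
#' @param transient_carrier_hz Carrier frequency of the transient Gabor.
#' @param on_amp,off_amp Transient amplitudes in units of the resting
#'   alpha source amplitude.
#' @param preservation_periods Integer range (length 2) of periods the
#'   driven rhythm persists after the last flash before decaying.
#' @param engagement_periods Periods over which the locked response ramps
#'   up after train onset.
#' @param alpha_recruitment Residual free-alpha amplitude factor at train
#'   onset of entrained blocks (the free rhythm is progressively
#'   recruited into the locked response).
#' @param alpha_suppression Free-alpha amplitude factor during fused
#'   (perceived-steady) stimulation, emulating event-related
#'   desynchronization.
#' @param alpha_recovery_s Time constant (s) over which the free alpha
#'   rhythm regains its resting amplitude after a stimulation train.
#' @param preservation_decay_periods Exponential decay constant (in
#'   stimulation periods) of the driven response after the preservation
#'   periods.
#' @param alpha_wander_hz,background_freq_hz,background_amp,
#'   background_freq_wander_hz,background_amp_wander Slow-wander model of
#'   the two incoherent oscillators: a posterior alpha rhythm and an
#'   anterior beta-range background, both with slowly drifting frequency
#'   and amplitude.
#' @param snr Sensor signal-to-noise scale: per-channel noise SD equals
#'   the per-type RMS topography weight divided by `snr`. Use `Inf` for
#'   noiseless data.
#' @param seed Integer seed for every random element of the generator.
#' @return An object of class `response_model_params`.
#' @export
response_model_params <- function(entrainment_band = c(0.40, 1.10),
                                  fusion_threshold_mult = 1.30,
                                  resonance_gains = NULL,
                                  gain_base = 1.3,
                                  gain_alpha = 2.2,
                                  gain_alpha_width = 0.07,
                                  gain_half = 1.2,
                                  gain_half_width = 0.05,
                                  resonance_gain_min = 2,
                                  on_latency_ms = 200,
                                  off_latency_ms = 150,
                                  latency_jitter_sd_ms = 18,
                                  transient_width_ms = 50,
                                  transient_carrier_hz = 10,
                                  on_amp = 3,
                                  off_amp = 1.5,
                                  preservation_periods = c(1L, 3L),
                                  engagement_periods = 7,
                                  alpha_recruitment = 0.15,
                                  alpha_suppression = 0.5,
                                  alpha_wander_hz = 0.4,
                                  alpha_recovery_s = 2.5,
                                  preservation_decay_periods = 0.8,
                                  background_freq_hz = 22,
                                  background_amp = 2.2,
                                  background_freq_wander_hz = 1.5,
                                  background_amp_wander = 0.25,
                                  snr = 2,
                                  seed = 1L) {
  stopifnot(length(entrainment_band) == 2, entrainment_band[1] < entrainment_band[2],
            fusion_threshold_mult > entrainment_band[2],
            length(preservation_periods) == 2,
            preservation_periods[1] >= 0,
            preservation_periods[2] >= preservation_periods[1],
            snr > 0, engagement_periods > 0)
  structure(as.list(environment()), class = "response_model_params")
}

#' Resonance gain of the driven response at a multiplier
#'
#' Amplitude gain of the stimulus-locked oscillation relative to the
#' resting alpha amplitude. Returns 0 for multipliers outside the
#' entrainment band or at/above the fusion threshold (no driven
#' oscillation).
#'
#' @param multiplier Stimulation-frequency multiplier(s).
#' @param params A `response_model_params`.
#' @return Numeric gain(s).
#' @export
resonance_gain <- function(multiplier, params) {
  stopifnot(inherits(params, "response_model_params"))
  g <- numeric(length(multiplier))
  inb <- multiplier >= params$entrainment_band[1] &
    multiplier <= params$entrainment_band[2] &
    multiplier < params$fusion_threshold_mult
  if (!is.null(params$resonance_gains)) {
    key <- format_multiplier(multiplier)
    hit <- inb & key %in% names(params$resonance_gains)
    g[hit] <- unname(params$resonance_gains[key[hit]])
    inb <- inb & !hit
  }
  g[inb] <- params$gain_base +
    params$gain_alpha * exp(-(multiplier[inb] - 1.0)^2 / (2 * params$gain_alpha_width^2)) +
    params$gain_half * exp(-(multiplier[inb] - 0.5)^2 / (2 * params$gain_half_width^2))
  g
}

#' Ground-truth labels implied by the response model
#'
#' @param multiplier Stimulation-frequency multiplier(s).
#' @param params A `response_model_params`.
#' @return Data frame with columns `multiplier`, `entrained`, `resonant`,
#'   `fused`, `gain`.
#' @export
ground_truth_labels <- function(multiplier, params) {
  g <- resonance_gain(multiplier, params)
  fused <- multiplier >= params$fusion_threshold_mult
  entrained <- multiplier >= params$entrainment_band[1] &
    multiplier <= params$entrainment_band[2] & !fused
  data.frame(
    multiplier = multiplier,
    entrained = entrained,
    resonant = entrained & g >= params$resonance_gain_min,
    fused = fused,
    gain = g
  )
}
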