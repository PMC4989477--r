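# Time-domain analysis: mean global field power, Hilbert envelope, and
# on-/off-response detection with group statistics.

#' Square root of mean global field power
#'
#' At each sample, the square root of the mean over channels of the
#' squared field value (the spatial RMS), computed over a single
#' channel type because fT and fT/cm cannot be mixed.
#'
#' @param x An `averaged_block`, `meg_recording`, or channels-by-samples
#'   matrix.
#' @param channel_type `"mag"` (default, matching the conventional MGFP
#'   display over magnetometers) or `"grad"`; ignored for plain
#'   matrices, which must already be single-type.
#' @return Numeric time series.
#' @export
mgfp <- function(x, channel_type = "mag") {
  data <- if (is.matrix(x)) {
    x
  } else {
    stopifnot(!is.null(x$layout))
    types <- unique(x$layout$type)
    if (!channel_type %in% types) stop("no channels of the requested type")
    x$data[x$layout$type == channel_type, , drop = FALSE]
  }
  sqrt(colMeans(data^2))
}

# Analytic signal via frequency-domain Hilbert transform.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Mean Hilbert envelope over all channels
#'
#' Computes the magnitude of the analytic signal per channel over the
#' window from 500 ms before the stimulation onset until 3 s after the
#' end of the stimulation (the default window of an averaged block),
#' then averages over all channels. Because magnetometer (fT) and
#' gradiometer (fT/cm) envelopes cannot be averaged raw, each channel
#' type is first standardized by its median envelope value.
#'
#' @param block An `averaged_block`.
#' @param window Integer sample indices (default: the whole block).
#' @param standardize Per-type standardization before averaging
#'   (default TRUE; has no effect on single-type data beyond a global
#'   scale).
#' @return An `envelope_ts`: list with `envelope` (dimensionless after
#'   standardization), `sfreq`, `window`, and the per-type scale
#'   factors.
#' @export
envelope <- function(block, window = NULL, standardize = TRUE) {
  stopifnot(inherits(block, "averaged_block"))
  n <- ncol(block$data)
  if (is.null(window)) window <- seq_len(n)
  window <- as.integer(window)
  if (any(window < 1) || any(window > n)) stop("window exceeds the block extent")
  x <- block$data[, window, drop = FALSE]
  env <- t(apply(x, 1, function(ch) Mod(analytic_signal(ch))))
  scales <- c(mag = 1, grad = 1)
  if (standardize) {
    for (tp in unique(block$layout$type)) {
      i <- block$layout$type == tp
      scales[tp] <- stats::median(env[i, ])
      if (scales[tp] > 0) env[i, ] <- env[i, ] / scales[tp]
    }
  }
  structure(list(envelope = colMeans(env), sfreq = block$sfreq,
                 window = window, type_scales = scales),
            class = "envelope_ts")
}

#' Detect on- and off-responses in a block envelope
#'
#' The on-response is the first local maximum of the channel-mean
#' envelope after the stimulation onset that exceeds the baseline mean
#' plus `k` baseline standard deviations (baseline: the 500 ms before
#' the onset); the off-response is the first such maximum after the end
#' of the stimulation. A qualifying peak must additionally be
#' *outstanding*: its prominence over the immediately preceding
#' envelope minimum must itself exceed `k` baseline standard
#' deviations, so that ripples riding on an elevated or slowly drifting
#' envelope (e.g. the preserved driven response decaying after an
#' entrained train) are not mistaken for transients, and it must reach
#' at least `rel_frac` of the maximal envelope value inside its search
#' window, so that minor foothills preceding a dominant peak (such as
#' filter ringing ahead of a large transient) are not picked as the
#' "first" peak. The first and last 100 ms of
#' the envelope are excluded from the search (analytic-signal edge
#' effects), and so is a 100 ms guard after each reference event so
#' that latency is strictly positive.
#'
#' @param env An `envelope_ts` (or numeric envelope with `sfreq` given).
#' @param onset_sample Sample index (within the envelope window) of the
#'   first flash onset.
#' @param end_sample Sample index of the end of the last flash period.
#' @param sfreq Sampling rate (taken from `env` when available).
#' @param k Peak qualification threshold in baseline SDs (default 3).
#' @param rel_frac Minimum height of a qualifying peak as a fraction of
#'   the maximal envelope in the search window (default 0.5).
#' @param baseline_s Baseline duration before onset (default 0.5).
#' @param edge_s Edge exclusion (default 0.1).
#' @param search_s Maximum search extent after each reference event
#'   (default 1 s for on, 3 s for off, clipped to the data).
#' @return List of two `transient_response`s (`on`, `off`), each with
#'   `detected`, `latency_ms`, `amplitude`, `threshold`.
#' @export
detect_on_off <- function(env, onset_sample, end_sample, sfreq = NULL,
                          k = 3, rel_frac = 0.5, baseline_s = 0.5,
                          edge_s = 0.1, search_s = c(on = 1, off = 3)) {
  if (inherits(env, "envelope_ts")) {
    sfreq <- env$sfreq
    env <- env$envelope
  }
  if (is.null(sfreq)) stop("sfreq required for a raw envelope vector")
  n <- length(env)
  edge <- round(edge_s * sfreq)
  base_i <- seq(max(edge + 1, onset_sample - round(baseline_s * sfreq)),
                onset_sample - 1)
  if (length(base_i) < 2) stop("envelope does not cover the pre-onset baseline")
  base_sd <- stats::sd(env[base_i])
  thr <- mean(env[base_i]) + k * base_sd
  peaks <- local_maxima(env)
  valleys <- local_maxima(-env)

  first_peak <- function(ref, horizon_s) {
    lo <- ref + edge
    hi <- min(n - edge, ref + round(horizon_s * sfreq))
    cand <- peaks[peaks >= lo & peaks <= hi & env[peaks] > thr]
    if (length(cand)) {
      cand <- cand[env[cand] >= rel_frac * max(env[lo:hi])]
    }
    # prominence over the immediately preceding envelope minimum
    prev_min <- if (length(cand)) {
      vapply(cand, function(p) {
        v <- valleys[valleys < p & valleys > ref]
        if (length(v)) env[max(v)] else env[ref]
      }, 0)
    } else numeric(0)
    cand <- cand[env[cand] - prev_min > k * base_sd]
    if (!length(cand)) {
      return(structure(list(detected = FALSE, latency_ms = NA_real_,
                            amplitude = NA_real_, threshold = thr),
                       class = "transient_response"))
    }
    p <- cand[1]
    structure(list(detected = TRUE,
                   latency_ms = (p - ref) / sfreq * 1000,
                   amplitude = env[p], threshold = thr),
              class = "transient_response")
  }
  pick <- function(nm, pos) {
    if (!is.null(names(search_s)) && nm %in% names(search_s)) {
      unname(search_s[[nm]])
    } else {
      unname(search_s[pos])
    }
  }
  list(on = first_peak(onset_sample, pick("on", 1)),
       off = first_peak(end_sample, pick("off", 2)))
}

#' @export
print.transient_response <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("Transient response: latency %.1f ms, amplitude %.3g (threshold %.3g)\n",
                x$latency_ms, x$amplitude, x$threshold))
  } else {
    cat(sprintf("No qualifying transient (threshold %.3g)\n", x$threshold))
  }
  invisible(x)
}

#' Group test of off-response occurrence: high vs low frequencies
#'
#' Per subject, the proportion of blocks with a detected off-response
#' among the low-multiplier group (<= `low_max`) and among the
#' high-multiplier group (>= `high_min`), compared with a one-sided
#' paired t-test (alternative: off-responses are more frequent at high
#' stimulation frequencies, i.e. above the flicker fusion threshold).
#' Additionally, a per-multiplier one-way ANOVA of on-response latency
#' and amplitude.
#'
#' @param responses Data frame with columns `subject`, `multiplier`,
#'   `off_detected` (logical), and optionally `on_detected`,
#'   `on_latency_ms`, `on_amplitude`.
#' @param low_max,high_min Group boundaries (defaults 1.10 and 1.30).
#' @return List with `per_subject` proportions, `t` and `p` of the
#'   paired test (p = 1 and `degenerate = TRUE` when all differences
#'   are zero), and `anova_on` (per-multiplier ANOVA of on-latency and
#'   amplitude, when available).
#' @export
test_off_occurrence <- function(responses, low_max = 1.10, high_min = 1.30) {
  stopifnot(all(c("subject", "multiplier", "off_detected") %in% names(responses)))
  subjects <- unique(responses$subject)
  per <- do.call(rbind, lapply(subjects, function(s) {
    d <- responses[responses$subject == s, ]
    low <- d$off_detected[d$multiplier <= low_max]
    high <- d$off_detected[d$multiplier >= high_min]
    if (!length(low) || !length(high)) {
      warning(sprintf("subject %s missing a frequency group; excluded", s))
      return(NULL)
    }
    data.frame(subject = s, prop_low = mean(low), prop_high = mean(high))
  }))
  if (is.null(per) || nrow(per) < 2) stop("need >= 2 subjects with both groups")
  d <- per$prop_high - per$prop_low
  if (stats::sd(d) == 0) {
    out <- list(per_subject = per, t = if (all(d == 0)) 0 else NA_real_,
                p = 1, degenerate = TRUE)
  } else {
    tt <- stats::t.test(per$prop_high, per$prop_low, paired = TRUE,
                        alternative = "greater")
    out <- list(per_subject = per, t = unname(tt$statistic), p = tt$p.value,
                degenerate = FALSE)
  }
  if (all(c("on_latency_ms", "on_amplitude") %in% names(responses))) {
    on <- responses[!is.na(responses$on_latency_ms), ]
    if (nrow(on) > length(unique(on$multiplier)) && length(unique(on$multiplier)) > 1) {
      out$anova_on <- list(
        latency = summary(stats::aov(on_latency_ms ~ factor(multiplier), data = on)),
        amplitude = summary(stats::aov(on_amplitude ~ factor(multiplier), data = on))
      )
    }
  }
  out
}
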