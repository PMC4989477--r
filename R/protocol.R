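#' Default stimulation-frequency multipliers
#'
#' The 20 stimulation frequencies are expressed as multiples of the
#' individual alpha frequency, densely sampled around 0.5 and 1.0 (where
#' subharmonic and fundamental resonance are expected) and around 2.0
#' (where rod-driven flicker perception has fused).
#'
#' @return Numeric vector of 20 dimensionless multipliers.
#' @export
default_multipliers <- function() {
  c(0.40, 0.45, 0.50, 0.55, 0.60, 0.70, 0.80, 0.90, 0.95, 1.00,
    1.05, 1.10, 1.30, 1.70, 1.90, 1.95, 2.00, 2.05, 2.10, 2.30)
}

#' Construct an IPS stimulation protocol
#'
#' Defines the session structure of a photic-driving experiment: each of
#' the 20 stimulation frequencies (multiples of the individual alpha
#' frequency `alpha_hz`) is presented in one block of `trains_per_block`
#' trains of `flashes_per_train` flashes, with `inter_train_rest_s`
#' seconds of rest between trains. A resting-state segment of
#' `resting_duration_s` seconds precedes the stimulation.
#'
#' @param alpha_hz Individual alpha frequency in Hz (7--13).
#' @param multipliers Dimensionless stimulation-frequency multipliers.
#' @param trains_per_block Trains per frequency block.
#' @param flashes_per_train Flashes (stimulation periods) per train.
#' @param inter_train_rest_s Rest between trains, seconds.
#' @param inter_block_rest_s Rest between frequency blocks, seconds
#'   (metadata only; blocks are simulated as separate recordings).
#' @param resting_duration_s Duration of the eyes-closed resting segment.
#' @param sfreq_hz Sampling rate in Hz.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(alpha_hz,
                          multipliers = default_multipliers(),
                          trains_per_block = 30L,
                          flashes_per_train = 40L,
                          inter_train_rest_s = 4,
                          inter_block_rest_s = 120,
                          resting_duration_s = 60,
                          sfreq_hz = 1000) {
  if (!is.numeric(alpha_hz) || length(alpha_hz) != 1 || !is.finite(alpha_hz) ||
      alpha_hz < 7 || alpha_hz > 13) {
    stop("alpha_hz must be a single frequency in the plausible alpha band [7, 13] Hz")
  }
  stopifnot(all(multipliers > 0), trains_per_block >= 1, flashes_per_train >= 1,
            inter_train_rest_s > 0, sfreq_hz > 0)
  structure(list(
    alpha_hz = alpha_hz,
    multipliers = as.numeric(multipliers),
    trains_per_block = as.integer(trains_per_block),
    flashes_per_train = as.integer(flashes_per_train),
    inter_train_rest_s = inter_train_rest_s,
    inter_block_rest_s = inter_block_rest_s,
    resting_duration_s = resting_duration_s,
    sfreq_hz = sfreq_hz
  ), class = "stim_protocol")
}

#' Generate a randomized stimulation protocol
#'
#' Returns the default protocol with the 20 multipliers in a
#' seed-determined random presentation order (the order in which blocks
#' were presented; analyses index blocks by multiplier, not by position).
#'
#' @param alpha_hz Individual alpha frequency in Hz.
#' @param seed Integer seed controlling the presentation order.
#' @param ... Passed on to [stim_protocol()].
#' @return A `stim_protocol` with randomized `multipliers`.
#' @export
generate_protocol <- function(alpha_hz, seed, ...) {
  proto <- stim_protocol(alpha_hz, ...)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 101L))
  proto$multipliers <- sample(proto$multipliers)
  proto
}

# Save/restore the global RNG state so that package randomness is fully
# seed-driven without clobbering the caller's stream.
#' @keywords internal
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Stimulation frequencies of a protocol
#'
#' @param protocol A `stim_protocol`.
#' @return Named numeric vector of stimulation frequencies in Hz, one per
#'   multiplier.
#' @export
stim_frequencies <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  f <- protocol$alpha_hz * protocol$multipliers
  names(f) <- format_multiplier(protocol$multipliers)
  f
}

#' @keywords internal
format_multiplier <- function(m) sprintf("%.2f", m)

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "IPS protocol: alpha %.2f Hz, %d frequency blocks (%.2f-%.2f x alpha)\n",
    x$alpha_hz, length(x$multipliers), min(x$multipliers), max(x$multipliers)))
  cat(sprintf("  %d trains of %d flashes per block, %.1f s inter-train rest, %g Hz sampling\n",
              x$trains_per_block, x$flashes_per_train, x$inter_train_rest_s, x$sfreq_hz))
  invisible(x)
}
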