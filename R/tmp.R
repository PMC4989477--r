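# Topographic Matching Pursuit: multichannel Gabor-atom fitting with a
# shared (scale, translation, modulation) and per-channel amplitudes and
# phases; reference atom and correlation-coefficient sequences.

#' Build a Gabor time-frequency dictionary
#'
#' Discretized Gabor family `g(t) = K exp(-pi ((t-u)/s)^2) exp(i xi (t-u))`
#' over one analysis window: dyadic scales, translations on a
#' quarter-scale lattice per scale, and modulations linearly spaced over
#' 2--30 Hz with a step of at most `freq_step_hz`. Every atom's Gaussian
#' envelope is normalized to unit l2 norm. Atoms are stored in the
#' deterministic tie-break order (increasing modulation, then scale,
#' then translation).
#'
#' @param window_len Window length in samples (>= 8).
#' @param sfreq Sampling rate in Hz.
#' @param min_scale Smallest dyadic scale in samples (default 4).
#' @param freq_range Modulation range in Hz (default `c(2, 30)`).
#' @param freq_step_hz Modulation grid step in Hz (default 0.5).
#' @param translation_frac Translation lattice step as a fraction of the
#'   scale (default 1/4).
#' @return A `gabor_dictionary`: list with the parameter table
#'   (`s`, `u`, `xi` per atom), the complex atom matrix
#'   (`window_len` x n_atoms), and grid metadata.
#' @export
build_gabor_dictionary <- function(window_len, sfreq, min_scale = 4,
                                   freq_range = c(2, 30),
                                   freq_step_hz = 0.5,
                                   translation_frac = 1 / 4) {
  window_len <- as.integer(window_len)
  if (window_len < 8) stop("analysis window too short (< 8 samples)")
  if (min_scale > window_len) stop("window too short for the smallest scale")
  scales <- 2^(seq(ceiling(log2(min_scale)), floor(log2(window_len))))
  n_freq <- max(2, ceiling(diff(freq_range) / freq_step_hz) + 1)
  freqs <- seq(freq_range[1], min(freq_range[2], sfreq / 2 * 0.999),
               length.out = n_freq)
  xis <- 2 * pi * freqs / sfreq
  grid <- list()
  for (s in scales) {
    us <- unique(round(seq(1, window_len, by = max(1, round(s * translation_frac)))))
    grid[[length(grid) + 1]] <- expand.grid(u = us, s = s)
  }
  grid <- do.call(rbind, grid)
  pars <- merge(data.frame(xi = xis), grid)
  pars <- pars[order(pars$xi, pars$s, pars$u), c("s", "u", "xi")]
  rownames(pars) <- NULL
  t_idx <- seq_len(window_len)
  atoms <- matrix(0+0i, window_len, nrow(pars))
  for (j in seq_len(nrow(pars))) {
    atoms[, j] <- gabor_atom_waveform(window_len, pars$s[j], pars$u[j], pars$xi[j])
  }
  out <- structure(list(params = pars, atoms = atoms, window_len = window_len,
                        sfreq = sfreq, freq_step_hz = diff(freqs[1:2]),
                        freqs_hz = freqs, scales = scales),
                   class = "gabor_dictionary")
  out$gram_cache <- dictionary_gram(out)
  out
}

# Complex Gabor atom with unit-l2 Gaussian envelope; phase referenced to
# the envelope centre u.
#' @keywords internal
gabor_atom_waveform <- function(window_len, s, u, xi) {
  t_idx <- seq_len(window_len)
  env <- exp(-pi * ((t_idx - u) / s)^2)
  env <- env / sqrt(sum(env^2))
  env * exp(1i * xi * (t_idx - u))
}

#' @export
print.gabor_dictionary <- function(x, ...) {
  cat(sprintf("Gabor dictionary: %d atoms over %d samples (%g Hz); scales {%s}, %d modulations %.2f-%.2f Hz\n",
              nrow(x$params), x$window_len, x$sfreq,
              paste(x$scales, collapse = ", "), length(x$freqs_hz),
              min(x$freqs_hz), max(x$freqs_hz)))
  invisible(x)
}

#' Fit one multichannel Gabor atom (single Matching Pursuit iteration)
#'
#' Selects the dictionary atom `g` maximizing the total signal energy
#' captured over all channels, where per channel the energy is that of
#' the orthogonal projection of the (real) signal onto the
#' two-dimensional span of `env*cos(xi(t-u))` and `env*sin(xi(t-u))` --
#' the real waveforms the atom can represent. For well-modulated atoms
#' this criterion coincides with the summed squared complex inner
#' products `sum_c |<x_c, g>|^2` (up to the constant factor for real
#' signals); unlike the raw complex projection it is not biased toward
#' quasi-unmodulated atoms, so a planted dictionary atom is always
#' recovered exactly. The per-channel amplitude and phase are those of
#' the projected waveform `amp * env * cos(xi(t-u) + phase)` (phase
#' measured at the envelope centre). Exactly one atom is extracted; no
#' residual iteration is performed. Ties are broken deterministically
#' toward the lowest modulation, then smallest scale, then smallest
#' translation.
#'
#' @param window_data Channels-by-samples matrix over the analysis
#'   window (same length as the dictionary's window).
#' @param dict A [build_gabor_dictionary()].
#' @return A `tmp_atom`: list with `s`, `u`, `xi` (shared), `amps` and
#'   `phases` (per channel), the selection criterion value (captured
#'   energy summed over channels), and a `degenerate` flag for all-zero
#'   windows.
#' @export
fit_atom <- function(window_data, dict) {
  stopifnot(inherits(dict, "gabor_dictionary"))
  if (is.numeric(window_data) && is.null(dim(window_data))) {
    window_data <- matrix(window_data, nrow = 1)
  }
  if (ncol(window_data) != dict$window_len) {
    stop("window length does not match the dictionary")
  }
  if (!all(is.finite(window_data))) stop("window data must be finite")
  gram <- dictionary_gram(dict)
  proj <- window_data %*% Conj(dict$atoms)         # c = r1 - i r2, channels x atoms
  r1 <- Re(proj)
  r2 <- -Im(proj)
  # captured energy E = r' G^{-1} r per channel and atom
  E <- sweep(r1^2, 2, gram$g22 / gram$det, `*`) -
    sweep(r1 * r2, 2, 2 * gram$g12 / gram$det, `*`) +
    sweep(r2^2, 2, gram$g11 / gram$det, `*`)
  if (any(gram$singular)) {                        # quasi-unmodulated: cos-only span
    js <- which(gram$singular)
    E[, js] <- sweep(r1[, js, drop = FALSE]^2, 2, gram$g11[js], `/`)
  }
  crit <- colSums(E)
  best <- max(crit)
  if (best <= 1e-24) {
    p <- dict$params[1, ]
    return(new_tmp_atom(p$s, p$u, p$xi, rep(0, nrow(window_data)),
                        rep(0, nrow(window_data)), criterion = 0,
                        degenerate = TRUE, channel_names = rownames(window_data)))
  }
  j <- which(crit >= best * (1 - 1e-12))[1]        # params pre-sorted for tie-break
  if (gram$singular[j]) {
    a1 <- r1[, j] / gram$g11[j]
    a2 <- rep(0, nrow(window_data))
  } else {
    a1 <- (gram$g22[j] * r1[, j] - gram$g12[j] * r2[, j]) / gram$det[j]
    a2 <- (gram$g11[j] * r2[, j] - gram$g12[j] * r1[, j]) / gram$det[j]
  }
  new_tmp_atom(dict$params$s[j], dict$params$u[j], dict$params$xi[j],
               amps = sqrt(a1^2 + a2^2),
               phases = wrap_phase(atan2(-a2, a1)),
               criterion = crit[j], degenerate = FALSE,
               channel_names = rownames(window_data))
}

# Gram data of the real cos/sin span of each atom, cached on the
# dictionary: P = sum(env^2 exp(2i xi (t-u))) = colSums(atoms^2) gives
# G11 = (1+Re P)/2, G22 = (1-Re P)/2, G12 = Im(P)/2 (unit-norm envelope).
#' @keywords internal
dictionary_gram <- function(dict) {
  if (!is.null(dict$gram_cache)) return(dict$gram_cache)
  P <- colSums(dict$atoms^2)
  g11 <- (1 + Re(P)) / 2
  g22 <- (1 - Re(P)) / 2
  g12 <- Im(P) / 2
  det <- g11 * g22 - g12^2
  list(g11 = g11, g22 = g22, g12 = g12, det = det,
       singular = det < 1e-10)
}

#' @keywords internal
new_tmp_atom <- function(s, u, xi, amps, phases, criterion = NA_real_,
                         degenerate = FALSE, channel_names = NULL) {
  structure(list(s = s, u = u, xi = xi,
                 amps = as.numeric(amps), phases = as.numeric(phases),
                 criterion = criterion, degenerate = degenerate,
                 channel_names = channel_names),
            class = "tmp_atom")
}

#' @export
print.tmp_atom <- function(x, ...) {
  cat(sprintf("TMP atom: s=%g u=%g xi=%.4f rad/sample (%d channels, max amp %.3g)%s\n",
              x$s, x$u, x$xi, length(x$amps), max(x$amps),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Atom sequence of an averaged block (40 + 10 periods)
#'
#' Fits one TMP atom per stimulation period (windows of one period
#' length anchored at each of the 40 flash onsets) and one per each of
#' the 10 periods following the end of the stimulation (anchored at the
#' nominal period continuation times).
#'
#' @param block An `averaged_block`.
#' @param dict Optional dictionary; built for the block's period length
#'   when omitted.
#' @param n_post Number of post-stimulation periods (default 10).
#' @param ... Passed to [build_gabor_dictionary()] when `dict` is NULL.
#' @return List of `length(flash_onsets) + n_post` `tmp_atom`s, with the
#'   dictionary attached as attribute `dict`.
#' @export
atom_sequence <- function(block, dict = NULL, n_post = 10, ...) {
  stopifnot(inherits(block, "averaged_block"))
  L <- block$period_samples
  if (is.null(dict)) dict <- build_gabor_dictionary(L, block$sfreq, ...)
  last_on <- block$flash_onsets[length(block$flash_onsets)]
  post_frac <- block$sfreq / block$stim_freq_hz          # true period, samples
  anchors <- c(block$flash_onsets,
               last_on + round(seq_len(n_post) * post_frac))
  if (max(anchors) + L - 1 > ncol(block$data)) {
    stop(sprintf("insufficient post-stimulation window: need %d samples, have %d",
                 max(anchors) + L - 1, ncol(block$data)))
  }
  lapply(anchors, function(a) {
    fit_atom(block$data[, a:(a + L - 1), drop = FALSE], dict)
  })
}

#' Individual reference atom
#'
#' Parameter-wise average of the 40 stimulus-period atoms of the
#' 1.00 x alpha block: arithmetic means of scale, translation and
#' modulation; per-channel amplitudes averaged arithmetically and
#' phases averaged circularly (direction of the resultant vector).
#'
#' @param atoms List of `tmp_atom`s (the stimulus-period atoms only;
#'   post-stimulation atoms must be excluded by the caller).
#' @return A `tmp_atom`.
#' @export
reference_atom <- function(atoms) {
  if (!length(atoms)) stop("cannot average an empty atom list")
  stopifnot(all(vapply(atoms, inherits, TRUE, "tmp_atom")))
  nch <- length(atoms[[1]]$amps)
  stopifnot(all(vapply(atoms, function(a) length(a$amps), 0L) == nch))
  amps <- rowMeans(vapply(atoms, `[[`, numeric(nch), "amps"))
  resultant <- rowSums(vapply(atoms, function(a) exp(1i * a$phases),
                              complex(nch)))
  phases <- wrap_phase(Arg(resultant))
  phases[Mod(resultant) < 1e-12] <- 0
  new_tmp_atom(mean(vapply(atoms, `[[`, 0, "s")),
               mean(vapply(atoms, `[[`, 0, "u")),
               mean(vapply(atoms, `[[`, 0, "xi")),
               amps, phases,
               channel_names = atoms[[1]]$channel_names)
}

# Real single-channel waveform of an atom over a window.
#' @keywords internal
atom_waveform_real <- function(atom, channel, window_len) {
  t_idx <- seq_len(window_len)
  env <- exp(-pi * ((t_idx - atom$u) / atom$s)^2)
  nrm <- sqrt(sum(env^2))
  if (nrm == 0) return(numeric(window_len))
  env <- env / nrm
  atom$amps[channel] * env * cos(atom$xi * (t_idx - atom$u) + atom$phases[channel])
}

#' Correlation-coefficient sequences against the reference atom
#'
#' For every channel and every atom of the sequence, reconstructs the
#' real waveforms of the atom and of the reference atom over the
#' analysis window and takes the maximum over all lags of the absolute
#' normalized cross-correlation, a similarity in [0, 1]. Channels on
#' which either waveform has zero energy get coefficient 0.
#'
#' @param reference The reference `tmp_atom`.
#' @param atoms List of `tmp_atom`s (typically 40 + 10).
#' @param window_len Analysis window length in samples.
#' @return A `corr_seq`: list with `coefficients`
#'   (channels x atoms matrix in [0, 1]) and `channel_mean`.
#' @export
correlation_sequence <- function(reference, atoms, window_len) {
  stopifnot(inherits(reference, "tmp_atom"), length(atoms) >= 1)
  nch <- length(reference$amps)
  stopifnot(all(vapply(atoms, function(a) length(a$amps), 0L) == nch))
  n_atoms <- length(atoms)
  coef <- matrix(0, nch, n_atoms)
  ref_w <- lapply(seq_len(nch), function(c) atom_waveform_real(reference, c, window_len))
  ref_e <- vapply(ref_w, function(w) sum(w^2), 0)
  nfft <- next_pow2(2 * window_len)
  ref_f <- lapply(ref_w, function(w) stats::fft(c(w, numeric(nfft - window_len))))
  for (j in seq_len(n_atoms)) {
    for (c in seq_len(nch)) {
      w <- atom_waveform_real(atoms[[j]], c, window_len)
      e <- sum(w^2)
      if (e <= 0 || ref_e[c] <= 0) next
      xc <- stats::fft(stats::fft(c(w, numeric(nfft - window_len))) *
                         Conj(ref_f[[c]]), inverse = TRUE) / nfft
      coef[c, j] <- min(1, max(Mod(Re(xc))) / sqrt(e * ref_e[c]))
    }
  }
  rownames(coef) <- reference$channel_names
  structure(list(coefficients = coef,
                 channel_mean = colMeans(coef),
                 n_atoms = n_atoms, window_len = window_len),
            class = "corr_seq")
}

#' @export
print.corr_seq <- function(x, ...) {
  cat(sprintf("Correlation sequence: %d channels x %d periods; channel-mean range %.3f-%.3f\n",
              nrow(x$coefficients), x$n_atoms,
              min(x$channel_mean), max(x$channel_mean)))
  invisible(x)
}

#' Tabulate an atom sequence
#'
#' One row per atom: period index, shared parameters, criterion, plus
#' the per-channel amplitude and phase columns. Suitable for CSV export.
#'
#' @param atoms List of `tmp_atom`s.
#' @param subject,multiplier Optional identifiers prepended as columns.
#' @return A data frame.
#' @export
atoms_to_df <- function(atoms, subject = NA, multiplier = NA) {
  nch <- length(atoms[[1]]$amps)
  nms <- atoms[[1]]$channel_names %||% sprintf("ch%03d", seq_len(nch))
  rows <- lapply(seq_along(atoms), function(j) {
    a <- atoms[[j]]
    row <- data.frame(subject = subject, multiplier = multiplier, period = j,
                      s = a$s, u = a$u, xi = a$xi, criterion = a$criterion,
                      degenerate = a$degenerate)
    amp <- as.data.frame(as.list(stats::setNames(a$amps, paste0("amp_", nms))))
    ph <- as.data.frame(as.list(stats::setNames(a$phases, paste0("phase_", nms))))
    cbind(row, amp, ph)
  })
  do.call(rbind, rows)
}
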