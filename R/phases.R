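# Engagement/plateau/disengagement segmentation of correlation
# sequences and good/moderate/weak response classification.

#' Detect the three phases of a correlation sequence
#'
#' Operationalizes the engagement (rise), plateau and disengagement
#' (fall) structure as a three-segment piecewise fit: a straight line
#' over periods `1..phase1_end`, a constant over the plateau, and a
#' straight line over `phase3_start..n`, with exhaustive search over
#' both breakpoints (`phase3_start` is constrained to the
#' post-stimulation periods). Phases count as detected when
#' \enumerate{
#'   \item the rise amplitude (plateau level minus the mean of the
#'     first two periods, the pre-engagement level) and the fall
#'     amplitude (plateau level minus the mean of the disengagement
#'     segment) each exceed `rise_frac` of the plateau level,
#'   \item the engagement completes by period `max_phase1_end`, and
#'   \item the piecewise fit explains at least `min_fit_gain` of the
#'     variance left by a flat fit (so unstructured sequences are not
#'     segmented).
#' }
#'
#' @param seq A `corr_seq` (its channel mean is used) or a numeric
#'   sequence of coefficients (40 stimulus + `n - 40` post periods).
#' @param n_stim Number of stimulus periods (default 40).
#' @param rise_frac Detection fraction of the plateau level
#'   (default 0.15).
#' @param max_phase1_end Latest allowed engagement end (default 15).
#' @param min_fit_gain Minimum proportional SSE reduction of the
#'   piecewise fit over a flat fit (default 0.5).
#' @return A `phase_segmentation`: list with `detected`, `phase1_end`,
#'   `phase3_start`, `plateau_mean`, `plateau_variance`,
#'   `preservation_periods`, `fit_gain`, `rise_amp`, `fall_amp`.
#' @export
detect_phases <- function(seq, n_stim = 40, rise_frac = 0.15,
                          max_phase1_end = 15, min_fit_gain = 0.5) {
  if (inherits(seq, "corr_seq")) seq <- seq$channel_mean
  seq <- as.numeric(seq)
  n <- length(seq)
  stopifnot(n > n_stim + 1)
  idx <- seq_len(n)
  sse_flat <- sum((seq - mean(seq))^2)

  fit_line <- function(i) {
    if (length(i) < 2) return(list(fitted = seq[i], sse = 0))
    ft <- stats::lm.fit(cbind(1, i), seq[i])
    list(fitted = ft$fitted.values, sse = sum(ft$residuals^2),
         coef = ft$coefficients)
  }

  b1_grid <- 2:min(n_stim - 1, 20)
  b2_grid <- (n_stim + 1):n
  sse_grid <- matrix(NA_real_, length(b1_grid), length(b2_grid))
  for (i in seq_along(b1_grid)) {
    rise <- fit_line(1:b1_grid[i])
    for (j in seq_along(b2_grid)) {
      plat_i <- (b1_grid[i] + 1):(b2_grid[j] - 1)
      m <- mean(seq[plat_i])
      sse_grid[i, j] <- rise$sse + sum((seq[plat_i] - m)^2) +
        fit_line(b2_grid[j]:n)$sse
    }
  }
  # parsimony tie-break on the engagement end only: a rise line absorbs
  # plateau noise almost as well as the plateau constant, so the raw
  # argmin drifts late under noise. Among engagement ends within a
  # noise-scaled SSE tolerance of the optimum, prefer the earliest; the
  # tolerance uses a successive-difference estimate of the coefficient
  # noise over the mid-stimulus periods, so it vanishes for noiseless
  # sequences and exact recovery is preserved. The disengagement start
  # keeps the strict argmin.
  mid <- seq(max(1, n_stim %/% 2), n_stim)
  sigma2_hat <- stats::var(diff(seq[mid])) / 2
  sse_by_b1 <- apply(sse_grid, 1, min)
  i1 <- which(sse_by_b1 <= min(sse_by_b1) + 10 * sigma2_hat)[1]
  j2 <- which.min(sse_grid[i1, ])
  b1 <- b1_grid[i1]; b2 <- b2_grid[j2]
  best <- list(sse = sse_grid[i1, j2])
  plat_i <- (b1 + 1):(b2 - 1)
  plateau_mean <- mean(seq[plat_i])
  plateau_var <- stats::var(seq[plat_i])
  rise_amp <- plateau_mean - mean(seq[1:2])
  fall_amp <- plateau_mean - mean(seq[b2:n])
  fit_gain <- if (sse_flat > 0) 1 - best$sse / sse_flat else 0
  detected <- is.finite(plateau_mean) && plateau_mean > 0 &&
    rise_amp >= rise_frac * plateau_mean &&
    fall_amp >= rise_frac * plateau_mean &&
    b1 <= max_phase1_end &&
    fit_gain >= min_fit_gain
  structure(list(detected = detected,
                 phase1_end = b1, phase3_start = b2,
                 plateau_mean = plateau_mean,
                 plateau_variance = plateau_var,
                 preservation_periods = max(0L, min(10L, b2 - n_stim)),
                 fit_gain = fit_gain, rise_amp = rise_amp,
                 fall_amp = fall_amp, n_stim = n_stim),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("Phases detected: engagement ends at period %d, disengagement starts at %d (plateau %.3f, variance %.2g)\n",
                x$phase1_end, x$phase3_start, x$plateau_mean, x$plateau_variance))
  } else {
    cat(sprintf("No three-phase structure detected (fit gain %.2f, rise %.3f, fall %.3f)\n",
                x$fit_gain, x$rise_amp, x$fall_amp))
  }
  invisible(x)
}

#' Classify a photic-driving response as good, moderate or weak
#'
#' Good: all three phases detected and the plateau variance of the
#' channel-mean coefficients is below the threshold (default 0.004).
#' Moderate: phases detected but the variance is at/above the
#' threshold. Weak: no three-phase structure.
#'
#' @param seq A `corr_seq` or numeric coefficient sequence.
#' @param threshold Plateau variance threshold (default 0.004).
#' @param segmentation Optional precomputed [detect_phases()] result.
#' @param ... Passed to [detect_phases()].
#' @return A `response_class`: list with `label` (factor good/moderate/
#'   weak), `variance_used`, `phases_detected`, `segmentation`.
#' @export
classify_response <- function(seq, threshold = 0.004, segmentation = NULL, ...) {
  if (is.null(segmentation)) segmentation <- detect_phases(seq, ...)
  label <- if (!segmentation$detected) {
    "weak"
  } else if (segmentation$plateau_variance < threshold) {
    "good"
  } else {
    "moderate"
  }
  structure(list(label = factor(label, levels = c("good", "moderate", "weak")),
                 variance_used = segmentation$plateau_variance,
                 phases_detected = segmentation$detected,
                 threshold = threshold,
                 segmentation = segmentation),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("Response class: %s (plateau variance %.2g, threshold %.2g)\n",
              as.character(x$label), x$variance_used, x$threshold))
  invisible(x)
}

#' Compare modulation-parameter variances across phases
#'
#' Per subject, the variance of the atoms' modulation parameter within
#' each phase (I: engagement, II: plateau, III: disengagement), plus
#' paired t-tests of phase I vs II and phase III vs II variances across
#' subjects. During engagement and disengagement the fitted frequency
#' is expected to be unstable, so variances in phases I and III should
#' exceed the plateau variance.
#'
#' @param atom_seqs List (one per subject) of `tmp_atom` lists.
#' @param segmentations A single `phase_segmentation` or a list of one
#'   per subject.
#' @param sfreq Optional sampling rate: when given, modulations are
#'   converted from rad/sample to Hz before taking variances.
#' @param var_type `"sample"` (default) or `"population"` variance.
#' @return List with `per_subject` (data frame of phase variances) and
#'   `tests` (paired t-statistics), plus a `degenerate` flag when all
#'   variances are zero.
#' @export
compare_phase_variances <- function(atom_seqs, segmentations, sfreq = NULL,
                                    var_type = c("sample", "population")) {
  var_type <- match.arg(var_type)
  stopifnot(length(atom_seqs) >= 2)
  if (inherits(segmentations, "phase_segmentation")) {
    segmentations <- rep(list(segmentations), length(atom_seqs))
  }
  stopifnot(length(segmentations) == length(atom_seqs))
  vfun <- function(x) {
    if (length(x) < 2) return(NA_real_)
    v <- stats::var(x)
    if (var_type == "population") v <- v * (length(x) - 1) / length(x)
    v
  }
  per <- do.call(rbind, lapply(seq_along(atom_seqs), function(i) {
    xi <- vapply(atom_seqs[[i]], `[[`, 0, "xi")
    if (!is.null(sfreq)) xi <- xi * sfreq / (2 * pi)
    seg <- segmentations[[i]]
    n <- length(xi)
    ph1 <- 1:seg$phase1_end
    ph2 <- (seg$phase1_end + 1):(seg$phase3_start - 1)
    ph3 <- seg$phase3_start:n
    for (nm in c("ph1", "ph2", "ph3")) {
      if (length(get(nm)) < 2) {
        warning(sprintf("subject %d: phase %s has < 2 atoms; variance set to NA", i, nm))
      }
    }
    data.frame(subject = i, var_I = vfun(xi[ph1]), var_II = vfun(xi[ph2]),
               var_III = vfun(xi[ph3]))
  }))
  degenerate <- all(unlist(per[, c("var_I", "var_II", "var_III")]) == 0, na.rm = TRUE)
  paired_t <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    d <- a[ok] - b[ok]
    if (sum(ok) < 2 || stats::sd(d) == 0) {
      return(data.frame(t = NA_real_, p = NA_real_, n = sum(ok), degenerate = TRUE))
    }
    tt <- stats::t.test(a[ok], b[ok], paired = TRUE, alternative = "greater")
    data.frame(t = unname(tt$statistic), p = tt$p.value, n = sum(ok),
               degenerate = FALSE)
  }
  tests <- rbind(cbind(contrast = "I_vs_II", paired_t(per$var_I, per$var_II)),
                 cbind(contrast = "III_vs_II", paired_t(per$var_III, per$var_II)))
  list(per_subject = per, tests = tests, degenerate = degenerate)
}
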