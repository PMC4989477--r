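# Shared fixtures and independent oracles, all built in code at test time.

# Small problem sizes keep the default suite fast; the generator's
# response-model defaults are never changed here.
tiny_layout <- function(n_triplets = 6) meg_layout(n_triplets)

tiny_protocol <- function(alpha = 10.58, sfreq = 250, trains = 6) {
  stim_protocol(alpha, sfreq_hz = sfreq, trains_per_block = trains)
}

noiseless_params <- function(seed = 1, ...) {
  response_model_params(snr = Inf, seed = seed, ...)
}

run_preproc <- function(rec, proto) {
  detrend_baseline(epoch_and_average(bandpass(rec), proto))
}

# Independent oracle for fit_atom: naive per-atom projection of each
# channel onto the real span {env*cos(xi(t-u)), env*sin(xi(t-u))} via
# lm.fit, summing residual-energy reduction over channels. Shares no
# code with the package's matrix implementation.
oracle_fit_atom <- function(X, dict) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  N <- ncol(X)
  t_idx <- seq_len(N)
  best <- list(crit = -Inf)
  for (j in seq_len(nrow(dict$params))) {
    s <- dict$params$s[j]; u <- dict$params$u[j]; xi <- dict$params$xi[j]
    env <- exp(-pi * ((t_idx - u) / s)^2)
    env <- env / sqrt(sum(env^2))
    B <- cbind(env * cos(xi * (t_idx - u)), env * sin(xi * (t_idx - u)))
    crit <- 0
    for (c in seq_len(nrow(X))) {
      y <- X[c, ]
      fit <- stats::lm.fit(B, y)
      crit <- crit + sum(y^2) - sum(fit$residuals^2)
    }
    if (crit > best$crit + 1e-12) {
      best <- list(crit = crit, s = s, u = u, xi = xi)
    }
  }
  best
}

# Brute-force normalized cross-correlation maximum over all lags.
oracle_xcorr_max <- function(w1, w2) {
  n <- length(w1)
  e1 <- sum(w1^2); e2 <- sum(w2^2)
  if (e1 == 0 || e2 == 0) return(0)
  best <- 0
  for (lag in -(n - 1):(n - 1)) {
    i1 <- max(1, 1 + lag):min(n, n + lag)
    i2 <- i1 - lag
    r <- abs(sum(w1[i1] * w2[i2])) / sqrt(e1 * e2)
    if (r > best) best <- r
  }
  best
}

# Planted three-phase correlation sequence.
planted_corrseq <- function(rise_end = 8, fall_start = 43, plateau = 0.75,
                            start = 0.2, final = 0.25, jitter_sd = 0,
                            n = 50) {
  rise <- start + (plateau - start) * (seq_len(rise_end) / rise_end)^2
  fall <- final + (plateau - final) * exp(-seq_len(n - fall_start + 1) / 3)
  base <- c(rise, rep(plateau, fall_start - rise_end - 1), fall)
  # jitter is a plateau property: the rise/fall ramps stay clean
  plat_i <- (rise_end + 1):(fall_start - 1)
  base[plat_i] <- base[plat_i] + stats::rnorm(length(plat_i), 0, jitter_sd)
  pmax(0, pmin(1, base))
}
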