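#' Idealized Vectorview-style sensor layout
#'
#' Builds an idealized whole-head layout of sensor triplets (one
#' magnetometer plus two orthogonal planar gradiometers per site), with
#' 2-D topographic coordinates on the unit disk (nose up, y > 0 anterior)
#' and a region tag. The default layout has 102 triplets (306 channels)
#' of which the 12 most posterior triplets are tagged `occipital`, so
#' that exactly 24 gradiometers carry the occipital tag. Real helmet
#' geometry is not reproduced: downstream computations use only channel
#' type, region tag and the 2-D coordinates.
#'
#' Sites are placed on a sunflower (Fibonacci) lattice, which spreads
#' points quasi-uniformly over the disk.
#'
#' @param n_triplets Number of sensor sites (default 102).
#' @param n_occipital_triplets Number of posterior sites tagged
#'   `occipital`; the default scales the full layout's 12 sites
#'   proportionally for reduced layouts.
#' @return A `meg_layout`: data frame with columns `name`, `type`
#'   (`"mag"` or `"grad"`), `triplet`, `x`, `y`, `region`.
#' @export
meg_layout <- function(n_triplets = 102L,
                       n_occipital_triplets = max(1L, round(n_triplets * 12 / 102))) {
  n_triplets <- as.integer(n_triplets)
  stopifnot(n_triplets >= 2, n_occipital_triplets >= 1,
            n_occipital_triplets <= n_triplets)
  i <- seq_len(n_triplets)
  golden <- (1 + sqrt(5)) / 2
  r <- sqrt((i - 0.5) / n_triplets)
  th <- 2 * pi * i / golden^2
  x <- r * cos(th)
  y <- r * sin(th)
  occ <- rank(y, ties.method = "first") <= n_occipital_triplets
  region <- ifelse(occ, "occipital", "other")
  df <- data.frame(
    name = c(sprintf("T%03d_MAG", i), sprintf("T%03d_GR1", i), sprintf("T%03d_GR2", i)),
    type = rep(c("mag", "grad", "grad"), each = n_triplets),
    triplet = rep(i, 3L),
    x = rep(x, 3L),
    y = rep(y, 3L),
    region = rep(region, 3L),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$triplet, df$type, df$name), ]
  rownames(df) <- NULL
  structure(df, class = c("meg_layout", "data.frame"))
}

#' Channel indices of the occipital gradiometer subset
#'
#' The spectral analyses average amplitude spectra over the occipital
#' gradiometers (24 channels in the default layout).
#'
#' @param layout A `meg_layout`.
#' @return Integer vector of row indices into the layout.
#' @export
occipital_gradiometers <- function(layout) {
  stopifnot(inherits(layout, "meg_layout"))
  which(layout$type == "grad" & layout$region == "occipital")
}

# Dipolar field pattern over the 2-D layout: two Gaussian poles of
# opposite sign centred at `poles` (2x2 matrix, one pole per row).
# Returns one weight per layout row. Per channel type the weight
# subvector is scaled to l2 norm `gain[type]` (mag in fT, grad in
# fT/cm), so that competing source topographies contribute equal
# whole-head energy at equal source amplitude.
#' @keywords internal
dipolar_topography <- function(layout, poles, sigma = 0.35,
                               gain = c(mag = 250, grad = 18)) {
  d1 <- (layout$x - poles[1, 1])^2 + (layout$y - poles[1, 2])^2
  d2 <- (layout$x - poles[2, 1])^2 + (layout$y - poles[2, 2])^2
  w <- exp(-d1 / (2 * sigma^2)) - exp(-d2 / (2 * sigma^2))
  for (tp in c("mag", "grad")) {
    idx <- layout$type == tp
    nrm <- sqrt(sum(w[idx]^2))
    if (nrm > 0) w[idx] <- w[idx] / nrm * unname(gain[tp])
  }
  w
}

# Fixed source topographies: a posterior (occipito-parietal) dipole for
# the alpha/driven source and transients, and an anterior dipole for the
# background oscillator.
#' @keywords internal
posterior_topography <- function(layout, gain = c(mag = 250, grad = 18)) {
  dipolar_topography(layout, poles = rbind(c(-0.3, -0.78), c(0.3, -0.78)),
                     sigma = 0.35, gain = gain)
}

#' @keywords internal
anterior_topography <- function(layout, gain = c(mag = 250, grad = 18)) {
  dipolar_topography(layout, poles = rbind(c(-0.3, 0.78), c(0.3, 0.78)),
                     sigma = 0.35, gain = gain)
}

#' @export
print.meg_layout <- function(x, ...) {
  cat(sprintf("MEG layout: %d channels (%d mag, %d grad) in %d triplets; %d occipital gradiometers\n",
              nrow(x), sum(x$type == "mag"), sum(x$type == "grad"),
              length(unique(x$triplet)), length(occipital_gradiometers(x))))
  invisible(x)
}
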