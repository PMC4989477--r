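# Internal helpers shared across modules.

#' @keywords internal
next_pow2 <- function(n) {
  stopifnot(n >= 1)
  2^ceiling(log2(n))
}

# Deterministic sub-seed derivation; keeps values well inside 32-bit range.
#' @keywords internal
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) {
    s <- (s * 69069 + as.double(k) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

# Indices of strict interior local maxima of a numeric vector.
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursive merge of user options over defaults (named lists).
#' @keywords internal
modify_defaults <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  stopifnot(is.list(defaults), is.list(user))
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

# Wrap angles into (-pi, pi].
#' @keywords internal
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}
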