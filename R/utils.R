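# internal numerics shared across modules

# Gaussian smoothing along the columns of a (series x time) matrix with
# reflective boundary handling; sigma in samples. sigma = 0 is the identity.
gaussianSmoothRows <- function(m, sigmaSamples) {
  if (sigmaSamples <= 0) return(m)
  T <- ncol(m)
  rad <- max(1L, ceiling(4 * sigmaSamples))
  k <- exp(-0.5 * ((-rad):rad / sigmaSamples)^2)
  k <- k / sum(k)
  # reflective padding: indices mirror at both ends
  idx <- c(rev(seq_len(min(rad, T - 1)) + 1L), seq_len(T),
           T - seq_len(min(rad, T - 1)))
  if (rad >= T) { # very wide kernel relative to series: repeat reflection
    full <- idx
    while (length(full) < T + 2 * rad) full <- c(rev(full), full)
    idx <- full[seq_len(T + 2 * rad)]
  }
  mp <- m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), T)
  for (o in seq_along(k)) out <- out + k[o] * mp[, (o - 1L) + seq_len(T), drop = FALSE]
  out
}

# central differences along columns, one-sided at the ends; dt scales to
# per-second units
centralDiffRows <- function(m, dt) {
  T <- ncol(m)
  d <- matrix(0, nrow(m), T)
  if (T >= 3)
    d[, 2:(T - 1)] <- (m[, 3:T, drop = FALSE] - m[, 1:(T - 2), drop = FALSE]) / (2 * dt)
  d[, 1] <- (m[, 2] - m[, 1]) / dt
  d[, T] <- (m[, T] - m[, T - 1]) / dt
  d
}

# stage-specific seed derived from a master seed; stable across sessions and
# kept below 2^31
deriveSeed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 131) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
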