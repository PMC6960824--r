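#' @keywords internal
"_PACKAGE"

# Speed of light [m/s], used to convert probing frequency to wavelength.
.C_LIGHT <- 299792458

# Standard gravity [m/s^2], used by the fall kinematics.
.GRAVITY <- 9.80665

#' Free-fall drop duration
#'
#' Time for a point mass to fall `drop_height` metres from rest under
#' gravity, `t = sqrt(2 h / g)`. This closed form drives the torso drop
#' segment of simulated fall trajectories.
#'
#' @param drop_height Drop height in metres (non-negative).
#' @return Duration in seconds.
#' @examples
#' free_fall_duration(1.2) # ~0.49 s
#' @export
free_fall_duration <- function(drop_height) {
  stopifnot(is.numeric(drop_height), all(drop_height >= 0))
  sqrt(2 * drop_height / .GRAVITY)
}

# Deterministic per-record seed derivation: mixes a master seed with event
# and radar indices through a Lehmer-style step so that every record gets an
# independent, reproducible stream. Kept below 2^31 - 1 (R integer range).
derive_seed <- function(master, event = 0L, radar = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + as.numeric(event) * 9973 + as.numeric(radar) * 433) %% m
  as.integer(if (s == 0) 1 else s)
}

# Cubic smoothstep on [0, 1]; clamps outside.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Round half away from zero (display convention for percent metrics).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Lightweight structural hash used for pipeline stage caching: a canonical
# deparse of the object, so equality means "same configuration".
config_fingerprint <- function(x) {
  paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "")
}
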