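#' PCA quadrature demodulation
#'
#' Combines the two baseband quadratures of a record into a single motion
#' signal by projecting the mean-centred (I, Q) sample cloud onto its first
#' principal axis. This sidesteps the null/optimal detection point problem of
#' quadrature receivers (either single channel can lose sensitivity depending
#' on the subject's distance) without requiring the DC-offset compensation
#' that arc-tangent demodulation needs. PCA is fitted per record because the
#' null-point geometry changes with subject position.
#'
#' The component sign is fixed so that its correlation with the raw I channel
#' is non-negative (ties resolve to a positive peak value): scalograms use
#' magnitudes, so the sign only needs to be reproducible.
#'
#' @param record A `radar_record` (see [synthesize_record()]), or any list
#'   with numeric `i_channel`, `q_channel` and `sampling_rate`.
#' @return Object of class `motion_signal`: `samples` (zero mean),
#'   `sampling_rate`, `record_id`, `explained_variance_ratio` (share of total
#'   I/Q variance captured by the component) and `degenerate` (`TRUE` when
#'   both channels are constant, in which case the signal is all zeros and a
#'   warning is raised instead of an error so batch runs continue).
#' @examples
#' tr <- simulate_trajectory("squats", sampling_rate = 2000)
#' ms <- pca_demodulate(synthesize_record(tr, radar_config(1)))
#' ms$explained_variance_ratio
#' @export
pca_demodulate <- function(record) {
  i <- record$i_channel
  q <- record$q_channel
  if (length(i) == 0 || length(q) == 0) stop("empty channel")
  if (length(i) != length(q)) {
    stop("channel lengths differ: I has ", length(i), ", Q has ", length(q))
  }
  xy <- cbind(i, q)
  tot_var <- sum(apply(xy, 2, stats::var))
  if (tot_var < .Machine$double.eps) {
    warning("constant I/Q channels: returning degenerate zero motion signal")
    return(new_motion_signal(
      numeric(length(i)), record$sampling_rate, record$record_id,
      explained_variance_ratio = NA_real_, degenerate = TRUE
    ))
  }
  pc <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  s <- pc$x[, 1]
  # Sign convention: non-negative correlation with raw I, tie -> positive peak.
  ic <- i - mean(i)
  cr <- sum(s * ic)
  if (cr < 0 || (cr == 0 && max(s) < -min(s))) s <- -s
  new_motion_signal(
    as.numeric(s), record$sampling_rate, record$record_id,
    explained_variance_ratio = pc$sdev[1]^2 / tot_var, degenerate = FALSE
  )
}

new_motion_signal <- function(samples, sampling_rate, record_id = NULL,
                              explained_variance_ratio = NA_real_,
                              degenerate = FALSE) {
  structure(
    list(
      samples = samples,
      sampling_rate = sampling_rate,
      record_id = record_id,
      explained_variance_ratio = explained_variance_ratio,
      degenerate = degenerate
    ),
    class = "motion_signal"
  )
}

#' @export
print.motion_signal <- function(x, ...) {
  cat(sprintf(
    "<motion_signal> %d samples @ %g sps%s%s\n",
    length(x$samples), x$sampling_rate,
    if (!is.na(x$explained_variance_ratio)) {
      sprintf(", PC1 explains %.1f%% of I/Q variance",
              100 * x$explained_variance_ratio)
    } else {
      ""
    },
    if (isTRUE(x$degenerate)) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Butterworth filtering of the demodulated motion signal
#'
#' Zero-phase (forward-backward) Butterworth filtering of the motion signal.
#' The default — 5th-order high-pass with a 5 Hz cut-off — suppresses the
#' baseline trend, respiration, heartbeat and slow everyday movements, which
#' all live below 5 Hz, while fall signatures carry much higher frequencies.
#' A `"lowpass"` mode is available for comparison. Zero-phase filtering is
#' used because records are processed offline and it preserves the timing of
#' the fall onset in the scalogram.
#'
#' @param signal A `motion_signal` (or numeric vector with `sampling_rate`
#'   supplied).
#' @param cutoff_hz Cut-off frequency in Hz; the designed filter's amplitude
#'   response is -3.01 dB there, by Butterworth definition. Must lie strictly
#'   below Nyquist.
#' @param order Filter order (default 5).
#' @param mode `"highpass"` (default) or `"lowpass"`.
#' @param sampling_rate Required only when `signal` is a bare numeric vector.
#' @return A `motion_signal` with the same length and grid.
#' @export
filter_motion <- function(signal, cutoff_hz = 5, order = 5,
                          mode = c("highpass", "lowpass"),
                          sampling_rate = NULL) {
  mode <- match.arg(mode)
  if (inherits(signal, "motion_signal")) {
    x <- signal$samples
    fs <- signal$sampling_rate
    rid <- signal$record_id
  } else {
    x <- as.numeric(signal)
    fs <- sampling_rate
    rid <- NULL
    if (is.null(fs)) stop("sampling_rate required for bare numeric input")
  }
  nyq <- fs / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq)) {
    stop(
      "cutoff_hz (", cutoff_hz, " Hz) must lie in (0, Nyquist = ",
      nyq, " Hz)"
    )
  }
  filt <- signal::butter(order, cutoff_hz / nyq,
    type = if (mode == "highpass") "high" else "low"
  )
  # Zero-phase filtering with odd-reflection padding so start-up transients
  # decay inside the (discarded) pad, not inside the record. The mean is
  # removed first (and restored for the lowpass mode), which a high-pass
  # would reject anyway and which keeps the reflections small.
  n <- length(x)
  xm <- mean(x)
  x0 <- x - xm
  pad <- min(n - 1L, max(3L * (order + 1L), ceiling(6 * fs / cutoff_hz)))
  xp <- c(
    2 * x0[1] - x0[(pad + 1L):2L],
    x0,
    2 * x0[n] - x0[(n - 1L):(n - pad)]
  )
  yp <- signal::filtfilt(filt, xp)
  y <- yp[(pad + 1L):(pad + n)]
  if (mode == "lowpass") y <- y + xm
  out <- new_motion_signal(as.numeric(y), fs, rid,
    explained_variance_ratio = if (inherits(signal, "motion_signal")) {
      signal$explained_variance_ratio
    } else {
      NA_real_
    },
    degenerate = if (inherits(signal, "motion_signal")) signal$degenerate else FALSE
  )
  out
}

#' Amplitude response of the motion filter
#'
#' Complex frequency response of the (single-pass) Butterworth design used by
#' [filter_motion()], evaluated at the requested frequencies. Handy for
#' verifying the -3 dB point at the cut-off. Note [filter_motion()] applies
#' the filter forward and backward, squaring this magnitude response.
#'
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @inheritParams filter_motion
#' @return Numeric vector of amplitude gains (|H|) at `freq_hz`.
#' @export
motion_filter_response <- function(freq_hz, cutoff_hz = 5, order = 5,
                                   mode = c("highpass", "lowpass"),
                                   sampling_rate = 250) {
  mode <- match.arg(mode)
  nyq <- sampling_rate / 2
  stopifnot(cutoff_hz > 0, cutoff_hz < nyq)
  filt <- signal::butter(order, cutoff_hz / nyq,
    type = if (mode == "highpass") "high" else "low"
  )
  w <- 2 * pi * freq_hz / sampling_rate
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(filt$b * zz^(-(seq_along(filt$b) - 1))), complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(-(seq_along(filt$a) - 1))), complex(1))
  Mod(num / den)
}
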