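#' Synthesize a two-channel I/Q radar record from a trajectory
#'
#' Evaluates the CW Doppler baseband model: each scattering centre at radial
#' distance `R_k(t)` contributes a phasor of phase `4*pi*R_k(t) / lambda`, so
#'
#'   `i(t) = sum_k a_k(t) cos(4 pi R_k(t) / lambda) + DC_I + n_I(t)`
#'   `q(t) = sum_k a_k(t) sin(4 pi R_k(t) / lambda) + DC_Q + n_Q(t)`
#'
#' with amplitudes `a_k` scaled by the configured range law
#' (`(1/R)^amplitude_exponent`, inverse-square by default) and a scenario
#' occlusion factor. The phasor sum is evaluated on the oversampled
#' `simulation_rate` grid, band-limited to the analog detecting band with an
#' order-2 Butterworth band-pass (emulating the front-end amplifier and
#' anti-alias behaviour), decimated to `sampling_rate`, and finally DC
#' offsets and Gaussian receiver noise are added.
#'
#' @param trajectory A [simulate_trajectory()] result sampled at
#'   `config$simulation_rate`.
#' @param config A [radar_config()].
#' @param occlusion_factor Scalar amplitude attenuation in `(0, 1]` for
#'   targets partially hidden from this radar (default 1 = unoccluded).
#' @param subject_id Integer subject id stored in the record metadata.
#' @param record_id Character record identifier.
#' @param seed Integer seed for the receiver noise.
#' @return Object of class `radar_record`: `i_channel`, `q_channel` (length
#'   `duration * sampling_rate`), `sampling_rate`, `radar_id`, `subject_id`,
#'   `record_id`, `activity_class`, `label`, `fall_onset`, `seed`.
#' @examples
#' tr <- simulate_trajectory("still", sampling_rate = 2000)
#' rec <- synthesize_record(tr, radar_config(1, noise_sigma = 0))
#' length(rec$i_channel) # 2500
#' @export
synthesize_record <- function(trajectory,
                              config,
                              occlusion_factor = 1,
                              subject_id = 1L,
                              record_id = "rec",
                              seed = 1) {
  stopifnot(inherits(trajectory, "trajectory"), inherits(config, "radar_config"))
  if (trajectory$sampling_rate != config$simulation_rate) {
    stop(
      "trajectory grid (", trajectory$sampling_rate,
      " sps) incompatible with radar simulation_rate (",
      config$simulation_rate, " sps)"
    )
  }
  stopifnot(occlusion_factor > 0, occlusion_factor <= 1)

  ranges <- trajectory_ranges(trajectory, config$position)
  if (any(ranges <= 0)) stop("non-positive radial distance in trajectory")
  refl <- trajectory$reflectivity
  # Range-amplitude law normalized at 1.5 m so typical echoes are O(1).
  amp <- sweep(
    (1.5 / ranges)^config$amplitude_exponent, 2, refl, `*`
  ) * occlusion_factor
  phase <- 4 * pi * ranges / config$wavelength
  i_sim <- rowSums(amp * cos(phase))
  q_sim <- rowSums(amp * sin(phase))

  if (config$analog_filter) {
    nyq <- config$simulation_rate / 2
    bp <- signal::butter(2, config$band / nyq, type = "pass")
    i_sim <- signal::filtfilt(bp, i_sim)
    q_sim <- signal::filtfilt(bp, q_sim)
  }

  dec <- config$simulation_rate / config$sampling_rate
  keep <- seq(1, length(i_sim), by = dec)
  i_ch <- i_sim[keep]
  q_ch <- q_sim[keep]

  set.seed(as.integer(seed))
  n <- length(i_ch)
  i_ch <- i_ch + config$dc_offset_i + stats::rnorm(n, 0, config$noise_sigma)
  q_ch <- q_ch + config$dc_offset_q + stats::rnorm(n, 0, config$noise_sigma)

  structure(
    list(
      i_channel = i_ch,
      q_channel = q_ch,
      sampling_rate = config$sampling_rate,
      radar_id = config$radar_id,
      subject_id = as.integer(subject_id),
      record_id = record_id,
      activity_class = trajectory$activity_class,
      label = trajectory$label,
      fall_onset = trajectory$fall_onset,
      seed = as.integer(seed)
    ),
    class = "radar_record"
  )
}

#' @export
print.radar_record <- function(x, ...) {
  cat(sprintf(
    "<radar_record> %s: radar %d, subject %d, %s (%s), %d samples @ %g sps%s\n",
    x$record_id, x$radar_id, x$subject_id, x$activity_class, x$label,
    length(x$i_channel), x$sampling_rate,
    if (!is.null(x$fall_onset)) {
      sprintf(", fall onset %.2f s", x$fall_onset)
    } else {
      ""
    }
  ))
  invisible(x)
}
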