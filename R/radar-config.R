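#' Radar configuration
#'
#' Parameters of one continuous-wave Doppler bioradar: probing frequency,
#' position in the room, sampling rate of the digitizer and the analog
#' detecting band of the front-end amplifier. Defaults follow the two-radar
#' K-band setup: 24.107 GHz (radar 1, frontal view) and 24.065 GHz (radar 2,
#' lateral view), 250 samples/s per channel, 1-100 Hz detecting band, both
#' radars mounted 0.8 m above the floor with boresights at 90 degrees.
#'
#' @param radar_id Integer 1 or 2.
#' @param probing_frequency Carrier frequency in Hz. Defaults to 24.107e9 for
#'   radar 1 and 24.065e9 for radar 2.
#' @param position Numeric length-3 `(x, y, z)` position in metres. Defaults
#'   place radar 1 at the origin looking along +x and radar 2 at
#'   `(1.5, -1.5, 0.8)` looking along +y.
#' @param sampling_rate ADC sampling rate in samples/s (per channel).
#' @param band Length-2 analog detecting band `(low, high)` in Hz; must
#'   satisfy `0 < low < high <= sampling_rate / 2`.
#' @param dc_offset_i,dc_offset_q Constant channel offsets (arbitrary
#'   amplitude units) emulating receiver DC and clutter.
#' @param noise_sigma Standard deviation of additive Gaussian receiver noise.
#' @param amplitude_exponent Range-amplitude law exponent: echo amplitude
#'   scales as `(1 / range)^amplitude_exponent`. Default 2 (inverse square);
#'   0 disables range scaling.
#' @param analog_filter Logical; apply the order-2 Butterworth band-pass that
#'   emulates the analog front-end before digitization (default `TRUE`).
#' @param simulation_rate Internal oversampled rate in samples/s at which the
#'   baseband phase is evaluated and the analog band-pass applied before
#'   decimation to `sampling_rate`. Must be an integer multiple of
#'   `sampling_rate`.
#' @return An object of class `radar_config`.
#' @examples
#' radar_config(1)
#' radar_config(2, noise_sigma = 0)
#' @seealso [default_radar_configs()], [synthesize_record()]
#' @export
radar_config <- function(radar_id,
                         probing_frequency = NULL,
                         position = NULL,
                         sampling_rate = 250,
                         band = c(1, 100),
                         dc_offset_i = 0.4,
                         dc_offset_q = -0.25,
                         noise_sigma = 0.03,
                         amplitude_exponent = 2,
                         analog_filter = TRUE,
                         simulation_rate = 2000) {
  radar_id <- as.integer(radar_id)
  if (!radar_id %in% c(1L, 2L)) {
    stop("radar_id must be 1 or 2, got ", radar_id)
  }
  if (is.null(probing_frequency)) {
    probing_frequency <- if (radar_id == 1L) 24.107e9 else 24.065e9
  }
  if (is.null(position)) {
    position <- if (radar_id == 1L) c(0, 0, 0.8) else c(1.5, -1.5, 0.8)
  }
  stopifnot(
    probing_frequency > 0,
    sampling_rate > 0,
    length(position) == 3,
    length(band) == 2,
    noise_sigma >= 0
  )
  if (!(band[1] > 0 && band[1] < band[2])) {
    stop("band must satisfy 0 < low < high, got (", band[1], ", ", band[2], ")")
  }
  if (band[2] > sampling_rate / 2) {
    stop(
      "band high edge ", band[2], " Hz exceeds Nyquist ",
      sampling_rate / 2, " Hz"
    )
  }
  if (simulation_rate %% sampling_rate != 0) {
    stop(
      "simulation_rate (", simulation_rate,
      ") must be an integer multiple of sampling_rate (", sampling_rate, ")"
    )
  }
  wavelength <- .C_LIGHT / probing_frequency
  stopifnot(is.finite(wavelength), wavelength > 0)
  structure(
    list(
      radar_id = radar_id,
      probing_frequency = probing_frequency,
      wavelength = wavelength,
      position = as.numeric(position),
      sampling_rate = sampling_rate,
      band = as.numeric(band),
      dc_offset_i = dc_offset_i,
      dc_offset_q = dc_offset_q,
      noise_sigma = noise_sigma,
      amplitude_exponent = amplitude_exponent,
      analog_filter = isTRUE(analog_filter),
      simulation_rate = simulation_rate
    ),
    class = "radar_config"
  )
}

#' Default pair of radar configurations
#'
#' @param ... Arguments forwarded to both [radar_config()] calls (e.g.
#'   `noise_sigma = 0`).
#' @return List of two `radar_config` objects (frontal radar 1, lateral
#'   radar 2).
#' @export
default_radar_configs <- function(...) {
  list(radar_config(1, ...), radar_config(2, ...))
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(
    "<radar_config> radar %d: %.3f GHz (lambda %.2f mm), %g sps, band %g-%g Hz\n",
    x$radar_id, x$probing_frequency / 1e9, x$wavelength * 1e3,
    x$sampling_rate, x$band[1], x$band[2]
  ))
  cat(sprintf(
    "  position (%.2f, %.2f, %.2f) m, noise sigma %g, DC (%.2f, %.2f)\n",
    x$position[1], x$position[2], x$position[3],
    x$noise_sigma, x$dc_offset_i, x$dc_offset_q
  ))
  invisible(x)
}

#' Scenario configuration for the synthetic study design
#'
#' Describes the recording campaign the dataset generator emulates: five
#' subjects, 70 ten-second records each (35 with one fall episode, 35 with a
#' daily activity), falls of two types (slip, faint) performed in four
#' orientations at four target points 1.0-2.0 m from the radars, with target
#' points 3 and 4 partially occluded from radar 2.
#'
#' @param n_subjects Number of subjects (default 5).
#' @param records_per_subject Records per subject (default 70; falls get
#'   `ceiling(records_per_subject / 2)` of them).
#' @param target_points Numeric matrix `n x 2` of `(x, y)` floor positions in
#'   metres where activities are performed.
#' @param occluded_points Indices of target points only partially visible to
#'   `occluded_radar` (default points 3 and 4).
#' @param occluded_radar Radar id affected by occlusion (default 2).
#' @param occlusion_factor Scalar amplitude attenuation in `(0, 1]` applied
#'   to the occluded (point, radar) pairs (default 0.3).
#' @param orientations Fall orientations cycled over fall records.
#' @param duration Record duration in seconds (default 10).
#' @param subject_heights Heights in metres for the synthetic subjects
#'   (default evenly spans 1.64-1.85 m).
#' @param seed Master seed; all per-record seeds derive from it.
#' @return Object of class `scenario_config`.
#' @examples
#' sc <- scenario_config()
#' sc$n_subjects * sc$records_per_subject # 350 records
#' @export
scenario_config <- function(n_subjects = 5,
                            records_per_subject = 70,
                            target_points = NULL,
                            occluded_points = c(3, 4),
                            occluded_radar = 2,
                            occlusion_factor = 0.3,
                            orientations = c("backward", "forward", "left", "right"),
                            duration = 10,
                            subject_heights = NULL,
                            seed = 1) {
  stopifnot(
    n_subjects >= 1, records_per_subject >= 1, duration > 0,
    occlusion_factor > 0, occlusion_factor <= 1
  )
  if (is.null(target_points)) {
    # Four points 1.0-2.0 m from the frontal radar at the origin.
    target_points <- rbind(
      c(1.00, 0.30),
      c(1.30, 0.00),
      c(1.60, 0.30),
      c(2.00, 0.00)
    )
  }
  target_points <- as.matrix(target_points)
  stopifnot(ncol(target_points) == 2, nrow(target_points) >= 1)
  if (is.null(subject_heights)) {
    subject_heights <- if (n_subjects == 1) {
      1.75
    } else {
      seq(1.64, 1.85, length.out = n_subjects)
    }
  }
  stopifnot(length(subject_heights) == n_subjects)
  bad <- occluded_points[occluded_points > nrow(target_points)]
  if (length(bad)) {
    stop("occluded_points outside target_points range: ", toString(bad))
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      records_per_subject = as.integer(records_per_subject),
      target_points = target_points,
      occluded_points = as.integer(occluded_points),
      occluded_radar = as.integer(occluded_radar),
      occlusion_factor = occlusion_factor,
      orientations = orientations,
      duration = duration,
      subject_heights = subject_heights,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  total <- x$n_subjects * x$records_per_subject
  cat(sprintf(
    "<scenario_config> %d subjects x %d records = %d events (%d falls), %g s each\n",
    x$n_subjects, x$records_per_subject, total,
    x$n_subjects * ceiling(x$records_per_subject / 2), x$duration
  ))
  cat(sprintf(
    "  %d target points; occlusion factor %g for radar %d at points %s\n",
    nrow(x$target_points), x$occlusion_factor, x$occluded_radar,
    toString(x$occluded_points)
  ))
  invisible(x)
}

# Per-subject parameters derived from the scenario.
subject_params <- function(scenario, subject_id) {
  h <- scenario$subject_heights[subject_id]
  list(
    subject_id = as.integer(subject_id),
    height = h,
    # Taller/heavier subjects fall slightly faster than pure free fall is
    # slowed by bracing; small spread keeps subjects distinguishable.
    fall_speed = seq(0.9, 1.1, length.out = scenario$n_subjects)[subject_id],
    torso_height = 0.8 * h,
    torso_reflectivity = 1.0,
    limb_reflectivity = 0.35
  )
}
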