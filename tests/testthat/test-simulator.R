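test_that("trajectory rejects bad inputs", {
  expect_error(simulate_trajectory("moonwalk"), "moonwalk")
  expect_error(
    simulate_trajectory("fall_slip", fall_onset = 9.9),
    "too close to record end"
  )
  expect_error(
    simulate_trajectory("squats", fall_onset = 3),
    "non-fall"
  )
})

test_that("still trajectory has no motion and yields DC-only channels", {
  tr <- simulate_trajectory("still", sampling_rate = 2000, seed = 2)
  r <- trajectory_ranges(tr, c(0, 0, 0.8))
  expect_equal(max(r) - min(r), 0)

  rec <- synthesize_record(tr, radar_config(1, noise_sigma = 0))
  # Constant phase -> band-pass leaves only the DC offsets (edge transients
  # of the zero-phase filter excluded).
  mid <- 250:2250
  expect_lt(stats::sd(rec$i_channel[mid]), 1e-3)
  expect_lt(stats::sd(rec$q_channel[mid]), 1e-3)
  expect_equal(mean(rec$i_channel[mid]), 0.4, tolerance = 1e-2)
})

test_that("torso drop follows the free-fall closed form", {
  expect_equal(free_fall_duration(1.2), sqrt(2 * 1.2 / 9.80665))
  tr <- simulate_trajectory("fall_faint",
    fall_onset = 3, sampling_rate = 2000,
    seed = 5
  )
  z <- tr$positions[, "z", "torso"]
  # Drop height 1.4 -> 0.2 m for the default 1.75 m subject.
  expect_equal(max(z), 1.4, tolerance = 1e-9)
  t_bottom <- tr$times[which(z <= 0.2 + 0.005)[1]]
  expect_equal(t_bottom - 3, free_fall_duration(1.2), tolerance = 5e-3)
})

test_that("unspecified fall onsets are uniform over the feasible window", {
  onsets <- vapply(seq_len(1000), function(i) {
    simulate_trajectory("fall_slip", sampling_rate = 50, seed = i)$fall_onset
  }, numeric(1))
  win <- fall_onset_window(
    list(torso_height = 1.4, fall_speed = 1),
    duration = 10
  )
  expect_gte(min(onsets), win[1])
  expect_lte(max(onsets), win[2])
  ks <- suppressWarnings(
    stats::ks.test(onsets, "punif", min = win[1], max = win[2])
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("constant radial velocity produces the Doppler line 2v/lambda", {
  rc <- radar_config(1,
    noise_sigma = 0, dc_offset_i = 0, dc_offset_q = 0,
    amplitude_exponent = 0
  )
  for (v in c(0.3, 0.5)) {
    traj <- constant_velocity_trajectory(v, duration = 2)
    rec <- synthesize_record(traj, rc)
    x <- rec$i_channel - mean(rec$i_channel)
    spec <- Mod(stats::fft(x))[seq_len(length(x) / 2)]
    bin_hz <- rec$sampling_rate / length(x)
    peak_hz <- (which.max(spec) - 1) * bin_hz
    expect_equal(peak_hz, 2 * v / rc$wavelength, tolerance = bin_hz * 1.01)
  }
})

test_that("single scatterer without band-limiting keeps unit modulus", {
  rc <- radar_config(1,
    noise_sigma = 0, dc_offset_i = 0, dc_offset_q = 0,
    amplitude_exponent = 0, analog_filter = FALSE
  )
  traj <- constant_velocity_trajectory(0.4, duration = 2)
  rec <- synthesize_record(traj, rc)
  m <- rec$i_channel^2 + rec$q_channel^2
  expect_equal(max(m) - min(m), 0, tolerance = 1e-12)
})

test_that("lateral radar sees smaller radial velocity for boresight motion", {
  traj <- constant_velocity_trajectory(0.5,
    duration = 2, start_x = 1.9,
    z = 1.0
  )
  rc1 <- radar_config(1)
  rc2 <- radar_config(2)
  vr <- function(pos) abs(diff(trajectory_ranges(traj, pos)[, 1]))
  v1 <- vr(rc1$position)
  v2 <- vr(rc2$position)
  expect_true(all(v2 < v1))
})

test_that("occlusion strictly attenuates the echo", {
  tr <- simulate_trajectory("squats", sampling_rate = 2000, seed = 9)
  rc <- radar_config(2, noise_sigma = 0)
  full <- synthesize_record(tr, rc, occlusion_factor = 1)
  occl <- synthesize_record(tr, rc, occlusion_factor = 0.3)
  amp <- function(rec) stats::sd(rec$i_channel) + stats::sd(rec$q_channel)
  expect_lt(amp(occl), amp(full))
  expect_equal(amp(occl) / amp(full), 0.3, tolerance = 0.05)
})

test_that("dataset generator reproduces the study composition", {
  ds <- tiny_dataset()
  m <- ds$manifest
  expect_equal(nrow(m), 2 * 4 * 2) # subjects x events x radars
  expect_equal(sum(m$label == "fall"), nrow(m) / 2)
  expect_setequal(unique(m$radar_id), c(1, 2))
  for (rec in ds$records) {
    expect_length(rec$i_channel, 2500)
    expect_length(rec$q_channel, 2500)
  }
  # Labels and classes are consistent.
  expect_true(all((m$activity_class %in% fall_classes()) == (m$label == "fall")))
  expect_true(all(is.na(m$fall_onset_s) == (m$label == "not_fall")))
})

test_that("the generator is deterministic in the master seed", {
  sc <- scenario_config(n_subjects = 2, records_per_subject = 2, seed = 17)
  d1 <- generate_dataset(sc)
  d2 <- generate_dataset(sc)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(
    d1$records[[1]]$i_channel,
    d2$records[[1]]$i_channel
  )
  expect_identical(
    lapply(d1$records, `[[`, "q_channel"),
    lapply(d2$records, `[[`, "q_channel")
  )
})

test_that("scenario validation catches inconsistent setups", {
  expect_error(radar_config(3), "radar_id")
  expect_error(radar_config(1, band = c(1, 200)), "Nyquist")
  expect_error(radar_config(1, simulation_rate = 300), "multiple")
  expect_error(
    generate_dataset(scenario_config(n_subjects = 1, records_per_subject = 2),
      radar_configs = list(radar_config(1))
    ),
    "exactly two"
  )
  tr <- simulate_trajectory("still", sampling_rate = 1000)
  expect_error(synthesize_record(tr, radar_config(1)), "incompatible")
})
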