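#' Activity taxonomy
#'
#' Activity classes follow the study design: two fall types (slipping, loss
#' of consciousness) and seven daily activities (entering/exiting the room,
#' whole-body turning, arm movements, sitting down and standing up, leaning,
#' squats, lying down on a mat). `"still"` is a degenerate motionless class
#' used for diagnostics and testing.
#'
#' @return Character vector of class names.
#' @export
activity_classes <- function() {
  c(fall_classes(), daily_classes(), "still")
}

#' @rdname activity_classes
#' @export
fall_classes <- function() {
  c("fall_slip", "fall_faint")
}

#' @rdname activity_classes
#' @export
daily_classes <- function() {
  c(
    "enter_exit", "turning", "arm_movement", "sit_stand",
    "leaning", "squats", "lying_down"
  )
}

is_fall_class <- function(activity_class) {
  activity_class %in% fall_classes()
}

orientation_vector <- function(orientation) {
  switch(orientation,
    forward = c(1, 0),
    backward = c(-1, 0),
    left = c(0, 1),
    right = c(0, -1),
    stop("unknown orientation: ", orientation)
  )
}

#' Feasible fall-onset window
#'
#' Interval of onset times for which a fall completes its displacement well
#' inside the record: the torso drop (free-fall time scaled by the subject's
#' fall-speed factor) plus a settling margin must fit before the record ends,
#' and a short lead-in precedes the earliest onset. Onsets are drawn
#' uniformly from this window when unspecified, emulating fall start times
#' equally distributed along the record.
#'
#' @param subject Subject parameter list (see [simulate_trajectory()]); only
#'   `torso_height` and `fall_speed` are used.
#' @param duration Record duration in seconds.
#' @return Numeric `c(lo, hi)` in seconds.
#' @export
fall_onset_window <- function(subject, duration = 10) {
  t_drop <- free_fall_duration(subject$torso_height - 0.2) / subject$fall_speed
  lo <- 0.8
  hi <- duration - t_drop - 0.7
  if (hi <= lo) stop("record too short for a fall: duration ", duration, " s")
  c(lo, hi)
}

default_subject <- function() {
  list(
    subject_id = 1L, height = 1.75, fall_speed = 1.0,
    torso_height = 1.4, torso_reflectivity = 1.0, limb_reflectivity = 0.35
  )
}

#' Simulate a motion trajectory for one activity record
#'
#' Produces time-sampled 3-D positions of one to three point scattering
#' centres (torso, plus arm/leg where the activity involves limb motion) for
#' a single 10 s record. Falls are a gravitational torso drop from standing
#' height (~1.4 m for a 1.75 m subject) to 0.2 m with a horizontal
#' displacement along the fall orientation; a slip is preceded by a fast
#' horizontal jerk, a faint by slow pre-fall sway. Daily activities use the
#' slower patterns of the study taxonomy (walking approach, periodic limb
#' oscillation, controlled descent for lying down). Small sway and breathing
#' micro-motion are superimposed on every non-still class.
#'
#' @param activity_class One of [activity_classes()].
#' @param point Length-2 `(x, y)` floor position in metres where the activity
#'   is performed.
#' @param orientation Fall orientation, one of `"backward"`, `"forward"`,
#'   `"left"`, `"right"` (ignored for non-fall classes).
#' @param subject Subject parameter list with `height`, `torso_height`,
#'   `fall_speed`, `torso_reflectivity`, `limb_reflectivity`; default is a
#'   1.75 m reference subject.
#' @param duration Record duration in seconds.
#' @param sampling_rate Trajectory grid rate in samples/s. Use the radar's
#'   `simulation_rate` when the trajectory will be synthesized to baseband.
#' @param fall_onset Fall onset time in seconds; drawn uniformly from
#'   [fall_onset_window()] when `NULL`. Must be `NULL` for non-fall classes.
#' @param seed Integer seed for the per-record kinematic jitter.
#' @return Object of class `trajectory`: list with `times` (seconds),
#'   `positions` (array `n_times x 3 x n_centres`, metres), `reflectivity`
#'   (per centre), `activity_class`, `label`, `fall_onset`, `duration`,
#'   `sampling_rate`.
#' @examples
#' tr <- simulate_trajectory("fall_slip", seed = 7)
#' tr$fall_onset
#' @export
simulate_trajectory <- function(activity_class,
                                point = c(1.3, 0),
                                orientation = "forward",
                                subject = NULL,
                                duration = 10,
                                sampling_rate = 2000,
                                fall_onset = NULL,
                                seed = 1) {
  if (!activity_class %in% activity_classes()) {
    stop(
      "unknown activity_class: '", activity_class, "' (expected one of ",
      toString(activity_classes()), ")"
    )
  }
  if (is.null(subject)) subject <- default_subject()
  stopifnot(length(point) == 2, duration > 0, sampling_rate > 0)
  fall <- is_fall_class(activity_class)
  if (!fall && !is.null(fall_onset)) {
    stop("fall_onset given for non-fall class '", activity_class, "'")
  }
  set.seed(as.integer(seed))
  n <- round(duration * sampling_rate)
  t <- seq(0, by = 1 / sampling_rate, length.out = n)
  px <- point[1]
  py <- point[2]
  hz <- subject$torso_height

  if (fall) {
    win <- fall_onset_window(subject, duration)
    if (is.null(fall_onset)) {
      fall_onset <- stats::runif(1, win[1], win[2])
    } else if (fall_onset > win[2]) {
      stop(
        "fall_onset ", fall_onset, " s too close to record end (latest ",
        round(win[2], 3), " s for ", duration, " s record)"
      )
    }
  }

  # Kinematic jitter so no two records are identical.
  jit <- function(x, frac = 0.12) x * stats::runif(1, 1 - frac, 1 + frac)
  ph <- stats::runif(3, 0, 2 * pi)

  torso <- cbind(x = rep(px, n), y = rep(py, n), z = rep(hz, n))
  centres <- list()
  refl <- c(torso = subject$torso_reflectivity)

  if (activity_class != "still") {
    # Standing sway + respiration (chest displacement roughly horizontal).
    torso[, "x"] <- torso[, "x"] +
      0.008 * sin(2 * pi * jit(0.35) * t + ph[1]) +
      0.004 * sin(2 * pi * jit(0.27) * t + ph[2])
    torso[, "y"] <- torso[, "y"] + 0.006 * sin(2 * pi * jit(0.3) * t + ph[3])
  }

  add_arm <- function(dx, dz = 0.15) {
    arm <- torso
    arm[, "x"] <- arm[, "x"] + 0.15 + dx
    arm[, "z"] <- arm[, "z"] + dz
    arm
  }

  if (fall) {
    m <- subject$fall_speed
    t_drop <- free_fall_duration(hz - 0.2) / m
    u <- t - fall_onset
    dropping <- u >= 0 & u <= t_drop
    after <- u > t_drop
    z <- torso[, "z"]
    z[dropping] <- pmax(hz - 0.5 * .GRAVITY * (m * u[dropping])^2, 0.2)
    # Millimetre-scale residual oscillation after floor contact; a fallen
    # body is close to motionless, and even 2 mm is several radians of
    # two-way phase at a 12 mm wavelength.
    z[after] <- 0.2 + 0.002 * exp(-(u[after] - t_drop) / 0.3) *
      sin(2 * pi * 4 * (u[after] - t_drop))
    torso[, "z"] <- z
    # Horizontal displacement along the fall orientation during the drop.
    ov <- orientation_vector(orientation)
    disp <- 0.5 * smoothstep(u / t_drop)
    torso[, "x"] <- torso[, "x"] + ov[1] * disp
    torso[, "y"] <- torso[, "y"] + ov[2] * disp
    if (activity_class == "fall_slip") {
      # Fast pre-fall jerk of the feet slipping out.
      v <- (t - (fall_onset - 0.3)) / 0.3
      pre <- 0.22 * smoothstep(v)
      torso[, "x"] <- torso[, "x"] + ov[1] * pre
      torso[, "y"] <- torso[, "y"] + ov[2] * pre
    } else {
      # Slow pre-fall sway while losing consciousness.
      w <- exp(-((t - fall_onset + 1) / 0.8)^2)
      torso[, "x"] <- torso[, "x"] + ov[1] * 0.05 * w *
        sin(2 * pi * jit(0.5) * t + ph[1])
    }
    # Flailing arm during the drop.
    arm <- add_arm(0, dz = 0.2)
    flail <- numeric(n)
    flail[dropping] <- 0.15 * sin(2 * pi * 3.2 * u[dropping] / 1)
    arm[, "x"] <- arm[, "x"] + flail
    arm[, "z"] <- pmax(arm[, "z"], 0.25)
    centres$arm <- arm
    refl <- c(refl, arm = subject$limb_reflectivity)
  } else if (activity_class == "enter_exit") {
    speed <- jit(0.7)
    path <- 1.6
    t_in0 <- 0.4
    t_in1 <- t_in0 + path / speed
    t_out0 <- duration - 0.4 - path / speed
    prog_in <- pmin(pmax((t - t_in0) / (t_in1 - t_in0), 0), 1)
    prog_out <- pmin(pmax((t - t_out0) / (duration - 0.4 - t_out0), 0), 1)
    walk <- path * (1 - prog_in) + path * prog_out
    torso[, "x"] <- torso[, "x"] + walk
    # Swinging leg while walking.
    leg <- torso
    leg[, "z"] <- 0.5
    moving <- (prog_in > 0 & prog_in < 1) | (prog_out > 0 & prog_out < 1)
    leg[, "x"] <- leg[, "x"] + 0.3 * moving * sin(2 * pi * jit(1.6) * t + ph[1])
    centres$leg <- leg
    refl <- c(refl, leg = subject$limb_reflectivity)
  } else if (activity_class == "turning") {
    w <- smoothstep((t - 1.5) / 1) * smoothstep((duration - 1.5 - t) / 1)
    f <- jit(0.4)
    torso[, "x"] <- torso[, "x"] + 0.06 * w * cos(2 * pi * f * t + ph[1])
    torso[, "y"] <- torso[, "y"] + 0.06 * w * sin(2 * pi * f * t + ph[1])
    arm <- add_arm(0)
    arm[, "x"] <- arm[, "x"] + 0.2 * w * cos(2 * pi * f * t + ph[2])
    arm[, "y"] <- arm[, "y"] + 0.2 * w * sin(2 * pi * f * t + ph[2])
    centres$arm <- arm
    refl <- c(refl, arm = subject$limb_reflectivity)
  } else if (activity_class == "arm_movement") {
    w <- smoothstep((t - 1) / 0.8) * smoothstep((duration - 1 - t) / 0.8)
    arm <- add_arm(0)
    arm[, "x"] <- arm[, "x"] + 0.28 * w * sin(2 * pi * jit(1.3) * t + ph[1])
    arm[, "z"] <- arm[, "z"] + 0.12 * w * sin(2 * pi * jit(0.9) * t + ph[2])
    centres$arm <- arm
    refl <- c(refl, arm = subject$limb_reflectivity)
  } else if (activity_class == "sit_stand") {
    t1 <- jit(2.5)
    t2 <- jit(6.2)
    dz <- 0.45 * hz / 1.4
    down <- smoothstep((t - t1) / jit(1.1))
    up <- smoothstep((t - t2) / jit(1.1))
    torso[, "z"] <- torso[, "z"] - dz * down + dz * up
    torso[, "x"] <- torso[, "x"] - 0.15 * down + 0.15 * up
  } else if (activity_class == "leaning") {
    t1 <- jit(3)
    t2 <- jit(6)
    lean <- smoothstep((t - t1) / jit(1.2)) - smoothstep((t - t2) / jit(1.2))
    torso[, "x"] <- torso[, "x"] + 0.35 * lean
    torso[, "z"] <- torso[, "z"] - 0.15 * lean
  } else if (activity_class == "squats") {
    f <- jit(0.45)
    w <- smoothstep((t - 1.5) / 0.8) * smoothstep((8.5 - t) / 0.8)
    torso[, "z"] <- torso[, "z"] -
      0.45 * w * (0.5 - 0.5 * cos(2 * pi * f * (t - 1.5)))
    arm <- add_arm(0)
    arm[, "z"] <- torso[, "z"] + 0.15
    centres$arm <- arm
    refl <- c(refl, arm = subject$limb_reflectivity)
  } else if (activity_class == "lying_down") {
    t1 <- jit(3.5)
    dur <- max(jit(2.8), 2) # controlled descent, >= 2 s
    desc <- smoothstep((t - t1) / dur)
    torso[, "z"] <- torso[, "z"] - (hz - 0.2) * desc
    torso[, "x"] <- torso[, "x"] + 0.4 * desc
  }
  # "still": torso stays constant, no extra centres.

  pos <- array(
    0,
    dim = c(n, 3, 1 + length(centres)),
    dimnames = list(NULL, c("x", "y", "z"), c("torso", names(centres)))
  )
  pos[, , 1] <- torso
  for (k in seq_along(centres)) pos[, , k + 1] <- centres[[k]]

  structure(
    list(
      times = t,
      positions = pos,
      reflectivity = refl,
      activity_class = activity_class,
      label = if (fall) "fall" else "not_fall",
      fall_onset = if (fall) fall_onset else NULL,
      duration = duration,
      sampling_rate = sampling_rate
    ),
    class = "trajectory"
  )
}

#' Radial distances from a trajectory to a radar position
#'
#' @param trajectory A `trajectory` object.
#' @param position Length-3 radar position `(x, y, z)` in metres.
#' @return Matrix `n_times x n_centres` of radial distances in metres.
#' @export
trajectory_ranges <- function(trajectory, position) {
  stopifnot(inherits(trajectory, "trajectory"), length(position) == 3)
  pos <- trajectory$positions
  k <- dim(pos)[3]
  out <- vapply(seq_len(k), function(j) {
    sqrt((pos[, 1, j] - position[1])^2 +
      (pos[, 2, j] - position[2])^2 +
      (pos[, 3, j] - position[3])^2)
  }, numeric(dim(pos)[1]))
  matrix(out, ncol = k, dimnames = list(NULL, dimnames(pos)[[3]]))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s (%s), %g s @ %g sps, %d scattering centre(s)%s\n",
    x$activity_class, x$label, x$duration, x$sampling_rate,
    dim(x$positions)[3],
    if (!is.null(x$fall_onset)) {
      sprintf(", fall onset %.2f s", x$fall_onset)
    } else {
      ""
    }
  ))
  invisible(x)
}
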