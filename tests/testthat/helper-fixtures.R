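# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Small two-subject dataset: 2 subjects x 4 events x 2 radars = 16 records.
tiny_dataset <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- generate_dataset(
      scenario_config(n_subjects = 2, records_per_subject = 4, seed = 3)
    )
  }
  .fixture_cache$tiny
}

# Full study-design dataset (5 subjects x 70 events x 2 radars), used by the
# structural and benchmark acceptance checks.
full_dataset <- function(seed = 1) {
  key <- paste0("full_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_dataset(scenario_config(seed = seed))
  }
  .fixture_cache[[key]]
}

# Bare radar record from explicit channels (for preprocessing tests).
make_record <- function(i, q, sampling_rate = 250, record_id = "test") {
  structure(
    list(
      i_channel = i, q_channel = q, sampling_rate = sampling_rate,
      radar_id = 1L, subject_id = 1L, record_id = record_id,
      activity_class = "still", label = "not_fall", fall_onset = NULL,
      seed = 0L
    ),
    class = "radar_record"
  )
}

# Trajectory of a single scatterer approaching radar 1 along x at constant
# speed v (m/s), for Doppler-oracle tests.
constant_velocity_trajectory <- function(v, duration = 2, sim_rate = 2000,
                                         start_x = 2.0, z = 0.8) {
  n <- round(duration * sim_rate)
  t <- seq(0, by = 1 / sim_rate, length.out = n)
  pos <- array(0, dim = c(n, 3, 1),
               dimnames = list(NULL, c("x", "y", "z"), "torso"))
  pos[, 1, 1] <- start_x - v * t
  pos[, 3, 1] <- z
  structure(
    list(
      times = t, positions = pos, reflectivity = c(torso = 1),
      activity_class = "still", label = "not_fall", fall_onset = NULL,
      duration = duration, sampling_rate = sim_rate
    ),
    class = "trajectory"
  )
}

# Two visually distinct toy image classes rendered at the classifier's input
# size: "low" has energy along the bottom rows (slow motion), "burst" a
# broadband vertical stripe (fall-like transient).
make_toy_image <- function(class = c("low", "burst"), seed = 1) {
  class <- match.arg(class)
  set.seed(seed)
  img <- array(stats::runif(227 * 227 * 3, 0, 0.15), dim = c(227, 227, 3))
  if (class == "low") {
    rows <- 190:227
    img[rows, , 1] <- img[rows, , 1] + 0.7
  } else {
    cols <- sample(30:190, 1) + 0:14
    img[1:140, cols, 3] <- img[1:140, cols, 3] + 0.7
  }
  pmin(img, 1)
}

make_toy_set <- function(n_per_class, seed = 1) {
  imgs <- c(
    lapply(seq_len(n_per_class), function(i) make_toy_image("low", seed + i)),
    lapply(seq_len(n_per_class), function(i) make_toy_image("burst", 1000 + seed + i))
  )
  labels <- rep(c("not_fall", "fall"), each = n_per_class)
  list(images = imgs, labels = labels)
}

# Brute-force reference metrics from raw prediction/label vectors.
brute_force_metrics <- function(pred, lab) {
  tp <- sum(pred == "fall" & lab == "fall")
  fp <- sum(pred == "fall" & lab == "not_fall")
  tn <- sum(pred == "not_fall" & lab == "not_fall")
  fn <- sum(pred == "not_fall" & lab == "fall")
  c(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  )
}
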