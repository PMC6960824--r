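#' Write / read a radar record on disk
#'
#' A record is stored as two plain-text files: `<record_id>.csv` with the
#' `i`,`q` sample columns printed at full double precision (17 significant
#' digits, so the write/read round trip is bit-exact) and
#' `<record_id>.json` with the metadata sidecar.
#'
#' @param record A `radar_record`.
#' @param dir Directory to write into (created if needed).
#' @return `write_record`: the CSV path, invisibly. `read_record`: a
#'   `radar_record`.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "radar_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$record_id)
  csv <- paste0(base, ".csv")
  lines <- c("i,q", sprintf("%.17g,%.17g", record$i_channel, record$q_channel))
  writeLines(lines, csv)
  meta <- record[c(
    "sampling_rate", "radar_id", "subject_id", "record_id",
    "activity_class", "label", "fall_onset", "seed"
  )]
  meta$n_samples <- length(record$i_channel)
  jsonlite::write_json(meta, paste0(base, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(csv)
}

#' @rdname write_record
#' @param path Path to the record's `.csv` (or its basename without
#'   extension); the `.json` sidecar must sit alongside.
#' @export
read_record <- function(path) {
  base <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(base, ".csv")
  js <- paste0(base, ".json")
  if (!file.exists(csv)) stop("record file not found: ", csv)
  if (!file.exists(js)) stop("record metadata sidecar not found: ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  required <- c(
    "sampling_rate", "radar_id", "subject_id", "record_id",
    "activity_class", "label", "n_samples"
  )
  miss <- setdiff(required, names(meta))
  if (length(miss)) stop("record metadata missing field(s): ", toString(miss))
  if (!meta$label %in% c("fall", "not_fall")) {
    stop("invalid label in metadata: '", meta$label, "'")
  }
  dat <- utils::read.csv(csv, colClasses = "numeric")
  if (!all(c("i", "q") %in% names(dat))) {
    stop("record CSV must have columns 'i' and 'q'")
  }
  if (nrow(dat) != meta$n_samples) {
    stop(
      "channel length ", nrow(dat), " does not match metadata n_samples ",
      meta$n_samples
    )
  }
  structure(
    list(
      i_channel = dat$i,
      q_channel = dat$q,
      sampling_rate = meta$sampling_rate,
      radar_id = as.integer(meta$radar_id),
      subject_id = as.integer(meta$subject_id),
      record_id = meta$record_id,
      activity_class = meta$activity_class,
      label = meta$label,
      fall_onset = if (is.null(meta$fall_onset)) NULL else meta$fall_onset,
      seed = if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed)
    ),
    class = "radar_record"
  )
}

#' Write / read a whole dataset
#'
#' Writes every record (see [write_record()]), the manifest as
#' `manifest.csv`, and a `dataset.json` sidecar carrying the master seed and
#' a configuration fingerprint used for pipeline caching.
#'
#' @param dataset A `radar_dataset`.
#' @param dir Output directory.
#' @return `write_dataset`: `dir`, invisibly. `read_dataset`: a
#'   `radar_dataset` (scenario/radar configurations are not reconstructed
#'   from disk; the fingerprint in the sidecar identifies them).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "radar_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in dataset$records) write_record(rec, dir)
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      seed = dataset$seed,
      n_records = nrow(dataset$manifest),
      fingerprint = dataset_fingerprint(dataset$scenario, dataset$radar_configs)
    ),
    file.path(dir, "dataset.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

dataset_fingerprint <- function(scenario, radar_configs) {
  config_fingerprint(list(scenario = unclass(scenario),
                          radars = lapply(radar_configs, unclass)))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("manifest.csv not found in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  n_files <- length(list.files(dir, pattern = "\\.csv$")) - 1L # minus manifest
  if (n_files != nrow(manifest)) {
    stop(
      "manifest lists ", nrow(manifest), " records but ", n_files,
      " record files found"
    )
  }
  records <- lapply(manifest$record_id, function(id) {
    read_record(file.path(dir, id))
  })
  names(records) <- manifest$record_id
  side <- file.path(dir, "dataset.json")
  seed <- if (file.exists(side)) {
    as.integer(jsonlite::read_json(side)$seed)
  } else {
    NA_integer_
  }
  structure(
    list(
      records = records, manifest = manifest,
      scenario = NULL, radar_configs = NULL, seed = seed
    ),
    class = "radar_dataset"
  )
}

#' Write an experiment report as CSV + JSON
#'
#' @param report An `experiment_report` (see [run_experiment()]).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      table = report$table,
      confusions = lapply(report$confusions, unclass),
      split = unclass(report$split),
      fusion_rule = report$fusion_rule,
      seed = report$seed
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
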