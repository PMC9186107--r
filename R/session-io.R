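# Session bundle I/O. A session is stored as a directory of plain-text files:
#   manifest.json  - ids, sampling rates, dimensions, schema version
#   events.csv     - trial/period table
#   spikes.csv     - neurons x stimulus-periods counts (one row per neuron)
#   orientations.csv, eeg.csv (one column per electrode), eye.csv
#   ground_truth_*.csv - generator sidecar (synthetic sessions only)
# Numerics are written with 17 significant digits so floating-point fields
# round-trip exactly.

SCHEMA_VERSION <- "1.0"

fmt_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.na(df[[j]])] <- NA
      df[[j]] <- x
    }
  }
  df
}

write_csv17 <- function(df, path) {
  data.table::fwrite(fmt_num_df(as.data.frame(df)), path, na = "NA")
}

read_csv_plain <- function(path) {
  as.data.frame(data.table::fread(path, na.strings = "NA"))
}

#' Write a session bundle
#'
#' @param rec A `session_recording`.
#' @param path Directory to create for the bundle.
#' @param force Overwrite an existing bundle? Refused by default.
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path, force = FALSE) {
  validate_session_recording(rec)
  if (dir.exists(path) && length(list.files(path)) > 0 && !force) {
    sd_stop("exists_error",
            "bundle already exists at '%s' (use force = TRUE to overwrite)",
            path)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    session_id = rec$session_id,
    subject_id = rec$subject_id,
    eeg_rate = rec$eeg_rate,
    eye_rate = rec$eye_rate,
    duration_s = rec$duration_s,
    n_neurons = nrow(rec$spike_counts),
    n_electrodes = nrow(rec$eeg),
    n_stimulus_periods = ncol(rec$spike_counts),
    has_ground_truth = !is.null(rec$ground_truth))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_csv17(rec$events, file.path(path, "events.csv"))
  write_csv17(as.data.frame(rec$spike_counts),
              file.path(path, "spikes.csv"))
  write_csv17(data.frame(orientation = rec$orientations),
              file.path(path, "orientations.csv"))
  eeg_df <- as.data.frame(t(rec$eeg))
  names(eeg_df) <- sprintf("e%d", seq_len(nrow(rec$eeg)))
  write_csv17(eeg_df, file.path(path, "eeg.csv"))
  write_csv17(rec$eye, file.path(path, "eye.csv"))
  gt <- rec$ground_truth
  if (!is.null(gt)) {
    if (!is.null(gt$true_microsaccades)) {
      write_csv17(gt$true_microsaccades,
                  file.path(path, "ground_truth_microsaccades.csv"))
    }
    if (!is.null(gt$neuron_loadings)) {
      write_csv17(data.frame(neuron = seq_along(gt$neuron_loadings),
                             loading = gt$neuron_loadings),
                  file.path(path, "ground_truth_loadings.csv"))
    }
    if (!is.null(gt$latent)) {
      write_csv17(data.frame(time_s = gt$latent$time_s,
                             value = gt$latent$value,
                             timescale_sd_min = gt$latent$timescale_sd_min),
                  file.path(path, "ground_truth_latent.csv"))
    }
  }
  invisible(path)
}

#' Read a session bundle
#'
#' @param path Bundle directory written by [write_session()].
#' @return A validated `session_recording`.
#' @export
read_session <- function(path) {
  sd_check(dir.exists(path), "io_error", "no session bundle at '%s'", path)
  mf_path <- file.path(path, "manifest.json")
  sd_check(file.exists(mf_path), "schema_error", "missing field: manifest")
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  sd_check(identical(manifest$schema_version, SCHEMA_VERSION), "schema_error",
           "unrecognized bundle schema version '%s'", manifest$schema_version)
  for (f in c("eeg_rate", "eye_rate", "session_id", "subject_id")) {
    sd_check(!is.null(manifest[[f]]), "schema_error", "missing field: %s", f)
  }
  sd_check(manifest$eeg_rate > 0 && manifest$eye_rate > 0, "validation_error",
           "sampling rates must be positive")
  need <- function(file, field) {
    p <- file.path(path, file)
    sd_check(file.exists(p), "schema_error", "missing field: %s", field)
    p
  }
  events <- read_csv_plain(need("events.csv", "events"))
  events$outcome <- as.character(events$outcome)
  attr(events, "duration_s") <- manifest$duration_s
  spikes <- as.matrix(read_csv_plain(need("spikes.csv", "spike_counts")))
  orientations <- read_csv_plain(
    need("orientations.csv", "orientations"))$orientation
  eeg <- t(as.matrix(read_csv_plain(need("eeg.csv", "eeg"))))
  eye <- read_csv_plain(need("eye.csv", "eye"))
  gt <- NULL
  if (isTRUE(manifest$has_ground_truth)) {
    gt <- list()
    p <- file.path(path, "ground_truth_microsaccades.csv")
    if (file.exists(p)) gt$true_microsaccades <- read_csv_plain(p)
    p <- file.path(path, "ground_truth_loadings.csv")
    if (file.exists(p)) gt$neuron_loadings <- read_csv_plain(p)$loading
    p <- file.path(path, "ground_truth_latent.csv")
    if (file.exists(p)) {
      lat <- read_csv_plain(p)
      gt$latent <- structure(list(time_s = lat$time_s, value = lat$value,
                                  timescale_sd_min = lat$timescale_sd_min[1],
                                  step_s = diff(lat$time_s[1:2])),
                             class = "arousal_latent")
    }
  }
  session_recording(
    session_id = manifest$session_id, subject_id = manifest$subject_id,
    spike_counts = spikes, orientations = orientations,
    eeg = eeg, eeg_rate = manifest$eeg_rate,
    eye = eye, eye_rate = manifest$eye_rate,
    events = events, ground_truth = gt)
}

#' Export result tables as CSV
#'
#' Binned series are written with columns `bin_center_min`, `value`;
#' per-session statistics tables with one row per session.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written.
#' @export
export_results <- function(tables, out_dir) {
  sd_check(length(tables) > 0 && !is.null(names(tables)) &&
             all(nzchar(names(tables))), "invalid_parameter",
           "tables must be a nonempty named list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_csv17(tables[[nm]], p)
    paths <- c(paths, p)
  }
  paths
}
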