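#' Write a cohort to a plain-text dataset directory
#'
#' Each recording unit becomes two delimited text files: an EMG file with
#' columns `time_s, emg_uV` (task phase) plus a `_baseline` companion, and
#' an accelerometer file with columns `time_s, acc_x_g, acc_y_g, acc_z_g`.
#' A `manifest.json` indexes every unit with its subject / skill / task /
#' trial / muscle / side / sampling-rate / MVC metadata.  Samples are
#' serialized with 17 significant digits so the round trip is exact.
#'
#' @param recordings list of [recording] objects (may be empty).
#' @param directory output directory, created if needed.
#' @return path to the manifest file, invisibly.
#' @export
write_dataset <- function(recordings, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    id <- recording_id(rec)
    emg_file <- paste0(id, ".csv")
    base_file <- paste0(id, "_baseline.csv")
    acc_file <- paste0(id, "_acc.csv")
    write_channel_csv(file.path(directory, emg_file),
                      c("time_s", "emg_uV"),
                      list((seq_along(rec$emg$samples) - 1) / rec$emg$fs,
                           rec$emg$samples))
    write_channel_csv(file.path(directory, base_file),
                      c("time_s", "emg_uV"),
                      list((seq_along(rec$baseline_emg$samples) - 1) /
                             rec$baseline_emg$fs,
                           rec$baseline_emg$samples))
    acc_fs <- rec$acc[[1]]$fs
    write_channel_csv(file.path(directory, acc_file),
                      c("time_s", "acc_x_g", "acc_y_g", "acc_z_g"),
                      c(list((seq_along(rec$acc[[1]]$samples) - 1) / acc_fs),
                        lapply(rec$acc, `[[`, "samples")))
    entries[[i]] <- list(subject = rec$subject_id, skill = rec$skill,
                         task = rec$task, trial = rec$trial,
                         muscle = rec$muscle, side = rec$side,
                         emg_fs = rec$emg$fs, acc_fs = acc_fs,
                         # serialized as text at full precision: the JSON
                         # writer's default digits would break exact round-trips
                         mvc_value = format_full(rec$mvc_value),
                         emg_file = emg_file, baseline_file = base_file,
                         acc_file = acc_file)
  }
  manifest <- file.path(directory, "manifest.json")
  jsonlite::write_json(list(format = "surgskill-dataset", version = 1L,
                            recordings = entries),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_channel_csv <- function(path, header, columns) {
  rows <- do.call(paste, c(lapply(columns, format_full), list(sep = ",")))
  con <- file(path, "wb")  # binary mode: fixed newline, reproducible checksum
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con)
}

read_channel_csv <- function(path, n_cols) {
  if (!file.exists(path)) {
    stop_invalid("corrupt dataset: missing channel file '%s'", path)
  }
  read.csv(path, colClasses = rep("numeric", n_cols))
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param directory dataset directory containing `manifest.json`.
#' @return list of [recording] objects (empty if the manifest lists none).
#' @export
read_dataset <- function(directory) {
  manifest <- file.path(directory, "manifest.json")
  if (!file.exists(manifest)) {
    stop_invalid("corrupt dataset: missing manifest '%s'", manifest)
  }
  meta <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  entries <- meta$recordings
  lapply(entries, function(e) {
    emg_df <- read_channel_csv(file.path(directory, e$emg_file), 2)
    base_df <- read_channel_csv(file.path(directory, e$baseline_file), 2)
    acc_df <- read_channel_csv(file.path(directory, e$acc_file), 4)
    recording(e$subject, e$skill, e$task, e$trial, e$muscle, e$side,
              emg = sensor_channel(emg_df$emg_uV, e$emg_fs, "emg"),
              acc = list(sensor_channel(acc_df$acc_x_g, e$acc_fs, "acc_x"),
                         sensor_channel(acc_df$acc_y_g, e$acc_fs, "acc_y"),
                         sensor_channel(acc_df$acc_z_g, e$acc_fs, "acc_z")),
              baseline_emg = sensor_channel(base_df$emg_uV, e$emg_fs, "emg"),
              mvc_value = as.numeric(e$mvc_value))
  })
}
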