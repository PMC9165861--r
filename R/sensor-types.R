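#' Sensor channel series
#'
#' One uniformly sampled sensor channel: surface EMG in microvolts or one
#' accelerometer axis in g.
#'
#' @param samples numeric vector of samples (uV for EMG, g for acceleration).
#' @param fs sampling rate in Hz (EMG is recorded at 2000 Hz, accelerometer
#'   axes at 100 Hz by default).
#' @param kind one of `"emg"`, `"acc_x"`, `"acc_y"`, `"acc_z"`.
#' @return object of class `sensor_channel` with fields `samples`, `fs`,
#'   `kind`.
#' @export
sensor_channel <- function(samples, fs, kind = c("emg", "acc_x", "acc_y", "acc_z")) {
  kind <- match.arg(kind)
  assert_finite_numeric(samples, "samples")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop_invalid("fs must be a single positive number, got %s", format(fs))
  }
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs), kind = kind),
            class = "sensor_channel")
}

#' @export
print.sensor_channel <- function(x, ...) {
  cat(sprintf("<sensor_channel %s: %d samples @ %g Hz (%.3f s)>\n",
              x$kind, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.sensor_channel <- function(x) length(x$samples)

SKILL_LEVELS <- c("novice", "intermediate", "expert")
TASKS <- c("knot_tying", "pegboard", "robotic_suturing")
MUSCLES <- c("biceps", "triceps", "deltoid", "ECU", "FCU", "TE")
SIDES <- c("left", "right")

#' Skill levels, tasks, muscle sites and sides used by the study design
#' @return character vector of levels.
#' @export
#' @rdname design-levels
skill_levels <- function() SKILL_LEVELS

#' @export
#' @rdname design-levels
task_names <- function() TASKS

#' @export
#' @rdname design-levels
muscle_names <- function() MUSCLES

#' One recording unit
#'
#' All channels for one (subject, skill, task, trial, muscle, side) unit:
#' the task-phase EMG channel, the three accelerometer axes, a resting
#' baseline EMG segment, and the muscle's MVC reference amplitude used for
#' envelope normalization.
#'
#' @param subject_id subject identifier string.
#' @param skill `"novice"`, `"intermediate"` or `"expert"`.
#' @param task `"knot_tying"`, `"pegboard"` or `"robotic_suturing"`.
#' @param trial positive integer trial index.
#' @param muscle one of `muscle_names()`.
#' @param side `"left"` or `"right"`.
#' @param emg [sensor_channel] of kind `"emg"`.
#' @param acc list of three [sensor_channel]s (`acc_x`, `acc_y`, `acc_z`).
#' @param baseline_emg resting-segment [sensor_channel] of kind `"emg"`,
#'   no longer than the task channel.
#' @param mvc_value positive MVC reference in envelope units (uV).
#' @return object of class `recording`.
#' @export
recording <- function(subject_id, skill, task, trial, muscle, side,
                      emg, acc, baseline_emg, mvc_value) {
  skill <- match.arg(skill, SKILL_LEVELS)
  task <- match.arg(task, TASKS)
  muscle <- match.arg(muscle, MUSCLES)
  side <- match.arg(side, SIDES)
  if (!inherits(emg, "sensor_channel") || emg$kind != "emg") {
    stop_invalid("emg must be a sensor_channel of kind 'emg'")
  }
  if (!is.list(acc) || length(acc) != 3 ||
      !all(vapply(acc, inherits, logical(1), "sensor_channel")) ||
      !identical(vapply(acc, `[[`, character(1), "kind"),
                 c("acc_x", "acc_y", "acc_z"))) {
    stop_invalid("acc must be a list of three sensor_channels acc_x/acc_y/acc_z")
  }
  if (!inherits(baseline_emg, "sensor_channel")) {
    stop_invalid("baseline_emg must be a sensor_channel")
  }
  if (length(baseline_emg$samples) > length(emg$samples)) {
    stop_invalid("baseline segment longer than the task channel")
  }
  if (!is.numeric(mvc_value) || length(mvc_value) != 1 || !is.finite(mvc_value) ||
      mvc_value <= 0) {
    stop_invalid("mvc_value must be a positive number")
  }
  trial <- as.integer(trial)
  if (is.na(trial) || trial < 1) stop_invalid("trial must be a positive integer")
  # all channels must cover the same wall-clock duration within one sample
  dur_emg <- length(emg$samples) / emg$fs
  dur_acc <- vapply(acc, function(a) length(a$samples) / a$fs, numeric(1))
  if (any(abs(dur_acc - dur_emg) > 1 / min(emg$fs, acc[[1]]$fs) + 1e-9)) {
    stop_invalid("EMG (%.3f s) and accelerometer (%.3f s) durations differ",
                 dur_emg, dur_acc[1])
  }
  structure(list(subject_id = as.character(subject_id), skill = skill,
                 task = task, trial = trial, muscle = muscle, side = side,
                 emg = emg, acc = acc, baseline_emg = baseline_emg,
                 mvc_value = as.numeric(mvc_value)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s/%s/%s trial %d %s-%s: emg %d @ %g Hz, acc %d @ %g Hz>\n",
              x$subject_id, x$skill, x$task, x$trial, x$side, x$muscle,
              length(x$emg$samples), x$emg$fs,
              length(x$acc[[1]]$samples), x$acc[[1]]$fs))
  invisible(x)
}

recording_id <- function(rec) {
  sprintf("%s_%s_%d_%s_%s", rec$subject_id, rec$task, rec$trial, rec$muscle, rec$side)
}
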