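#' Muscle activation profile
#'
#' Parameters of the burst-structured EMG model used by the synthetic cohort.
#' Skill groups differ in burst density, burst duration, contraction level
#' and task duration, which is what drives the group differences in
#' cumulative muscular workload and activation time downstream.
#'
#' @param burst_rate expected bursts per second.
#' @param burst_duration_mean mean burst duration in seconds.
#' @param burst_amplitude contraction level as a fraction of MVC, in (0, 1.5].
#' @param baseline_noise_sd additive baseline noise SD in uV.
#' @param task_duration task duration in seconds.
#' @return object of class `activation_profile`.
#' @export
activation_profile <- function(burst_rate, burst_duration_mean, burst_amplitude,
                               baseline_noise_sd, task_duration) {
  vals <- c(burst_rate = burst_rate, burst_duration_mean = burst_duration_mean,
            burst_amplitude = burst_amplitude,
            baseline_noise_sd = baseline_noise_sd, task_duration = task_duration)
  if (!all(is.finite(vals)) || any(vals[names(vals) != "baseline_noise_sd"] <= 0) ||
      baseline_noise_sd < 0) {
    stop_invalid("activation_profile fields must be positive (noise SD >= 0)")
  }
  if (burst_amplitude > 1.5) {
    stop_invalid("burst_amplitude must lie in (0, 1.5], got %g", burst_amplitude)
  }
  structure(as.list(vals), class = "activation_profile")
}

#' Movement complexity profile
#'
#' Mixture weights of the three-component accelerometer model: a sinusoid
#' (regular, well-practiced movement), a chaotic-flow trajectory (structured
#' but unpredictable corrections) and white noise (erratic motion).  The
#' weights are the knob that the entropy / Lyapunov / correlation-dimension
#' features respond to.
#'
#' @param periodic_weight,chaotic_weight,noise_weight non-negative weights
#'   summing to 1.
#' @param amplitude peak per-axis acceleration in g.
#' @param base_frequency sinusoid frequency in Hz (gross arm movement is in
#'   the 1-2 Hz range).
#' @return object of class `complexity_profile`.
#' @export
complexity_profile <- function(periodic_weight, chaotic_weight, noise_weight,
                               amplitude = 1, base_frequency = 1.5) {
  w <- c(periodic_weight, chaotic_weight, noise_weight)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_invalid("complexity weights must be non-negative")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop_invalid("complexity weights must sum to 1 (got %.12g)", sum(w))
  }
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop_invalid("amplitude must be positive")
  }
  structure(list(periodic_weight = w[1], chaotic_weight = w[2],
                 noise_weight = w[3], amplitude = amplitude,
                 base_frequency = base_frequency),
            class = "complexity_profile")
}

#' Default per-skill generator templates
#'
#' Novices co-contract more (denser, longer bursts), take longer on the
#' pegboard and robotic tasks, and move more erratically (heavier noise
#' component); experts are the opposite.  Knot tying takes all groups a
#' similar time, which the cohort generator applies as a task override.
#'
#' @return named list with one `activation` and one `complexity` profile per
#'   skill level.
#' @export
default_skill_templates <- function() {
  list(
    novice = list(
      activation = activation_profile(burst_rate = 1.2, burst_duration_mean = 1.0,
                                      burst_amplitude = 0.65,
                                      baseline_noise_sd = 2, task_duration = 32),
      complexity = complexity_profile(0.15, 0.40, 0.45)
    ),
    intermediate = list(
      activation = activation_profile(burst_rate = 0.9, burst_duration_mean = 0.7,
                                      burst_amplitude = 0.5,
                                      baseline_noise_sd = 2, task_duration = 24),
      complexity = complexity_profile(0.45, 0.35, 0.20)
    ),
    expert = list(
      activation = activation_profile(burst_rate = 0.6, burst_duration_mean = 0.5,
                                      burst_amplitude = 0.38,
                                      baseline_noise_sd = 2, task_duration = 18),
      complexity = complexity_profile(0.70, 0.25, 0.05)
    )
  )
}

#' Cohort configuration
#'
#' @param group_sizes named integer vector of subjects per skill group.  The
#'   default follows the study-design counts of 10 novices, 11 intermediates
#'   and 5 experts.
#' @param tasks subset of `task_names()`.
#' @param trials_per_task trials per (subject, task); at least three trials
#'   per task is the study convention.
#' @param muscles subset of `muscle_names()`.
#' @param sides `"left"`, `"right"` or both.
#' @param templates per-skill generator templates, see
#'   [default_skill_templates()].
#' @param jitter_sd between-subject log-normal jitter SD applied to
#'   activation parameters and complexity weights.
#' @param emg_fs,acc_fs sampling rates in Hz.
#' @param baseline_duration resting-segment duration in seconds.
#' @param duration_scale multiplier on template task durations (use < 1 for
#'   quick, reduced-size runs).
#' @param muscle_effects named vector in \[0, 1\] per muscle: 1 means the
#'   muscle expresses the full skill-group effect, 0 means its profiles are
#'   the skill-neutral (intermediate) template.  Unnamed muscles default
#'   to 1.
#' @param mvc_multiple MVC reference = this multiple of the subject's
#'   maximum task envelope amplitude for that muscle.
#' @param seed integer seed; every generated sample is a pure function of
#'   (config, seed).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(novice = 10, intermediate = 11, expert = 5),
                          tasks = task_names(),
                          trials_per_task = 3,
                          muscles = muscle_names(),
                          sides = c("left", "right"),
                          templates = default_skill_templates(),
                          jitter_sd = 0.08,
                          emg_fs = 2000, acc_fs = 100,
                          baseline_duration = 5,
                          duration_scale = 1,
                          muscle_effects = NULL,
                          mvc_multiple = 2,
                          seed = 1L) {
  if (!all(SKILL_LEVELS %in% names(group_sizes))) {
    stop_invalid("group_sizes must name every skill level")
  }
  if (any(group_sizes < 1)) stop_invalid("every skill group must be non-empty")
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  muscles <- match.arg(muscles, MUSCLES, several.ok = TRUE)
  sides <- match.arg(sides, SIDES, several.ok = TRUE)
  if (trials_per_task < 1) stop_invalid("trials_per_task must be >= 1")
  eff <- rep(1, length(MUSCLES))
  names(eff) <- MUSCLES
  if (!is.null(muscle_effects)) {
    if (is.null(names(muscle_effects)) || !all(names(muscle_effects) %in% MUSCLES)) {
      stop_invalid("muscle_effects must be named by muscle")
    }
    eff[names(muscle_effects)] <- muscle_effects
  }
  structure(list(group_sizes = group_sizes[SKILL_LEVELS], tasks = tasks,
                 trials_per_task = as.integer(trials_per_task),
                 muscles = muscles, sides = sides, templates = templates,
                 jitter_sd = jitter_sd, emg_fs = emg_fs, acc_fs = acc_fs,
                 baseline_duration = baseline_duration,
                 duration_scale = duration_scale,
                 muscle_effects = eff, mvc_multiple = mvc_multiple,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# band-limited Gaussian carrier occupying the 20-450 Hz analysis band, so
# the preprocessing band-pass leaves its energy intact
emg_carrier <- function(n, fs) {
  x <- rnorm(n)
  hi <- min(450, 0.45 * fs)
  bf <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / max(sd(y), .Machine$double.eps)
}

#' Generate one synthetic EMG channel
#'
#' Band-limited (20-450 Hz) zero-mean noise carrier multiplied by a
#' burst-train envelope plus additive baseline noise.  Burst count is
#' Poisson in `burst_rate * task_duration`, burst centres uniform, burst
#' shapes Gaussian.  The envelope is expressed in uV via a nominal MVC
#' amplitude of 400 uV scaled by `burst_amplitude`.
#'
#' @param profile [activation_profile].
#' @param fs sampling rate in Hz, at least 1000 so the carrier band fits.
#' @param seed integer seed; identical (profile, fs, seed) give bit-identical
#'   samples.
#' @param mvc_nominal nominal MVC amplitude in uV.
#' @return [sensor_channel] of kind `"emg"`.
#' @export
generate_emg_channel <- function(profile, fs = 2000, seed = 1L, mvc_nominal = 400) {
  if (!inherits(profile, "activation_profile")) {
    stop_invalid("profile must be an activation_profile")
  }
  if (fs < 1000) stop_invalid("fs must be >= 1000 Hz, got %g", fs)
  if (profile$task_duration <= 0) stop_invalid("task duration must be positive")
  n <- max(2L, round(profile$task_duration * fs))
  with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    env <- numeric(n)
    n_burst <- rpois(1, profile$burst_rate * profile$task_duration)
    if (n_burst > 0 && profile$burst_amplitude > 0) {
      centers <- runif(n_burst, 0, profile$task_duration)
      widths <- pmax(0.05, profile$burst_duration_mean * exp(rnorm(n_burst, 0, 0.25)))
      amps <- profile$burst_amplitude * mvc_nominal * runif(n_burst, 0.75, 1.25)
      for (b in seq_len(n_burst)) {
        s <- widths[b] / 2.355  # FWHM -> Gaussian sigma
        env <- env + amps[b] * exp(-0.5 * ((t - centers[b]) / s)^2)
      }
      # saturate stacked bursts at the contraction ceiling
      env <- pmin(env, 1.25 * profile$burst_amplitude * mvc_nominal)
    }
    carrier <- if (any(env > 0)) emg_carrier(n, fs) else numeric(n)
    noise <- if (profile$baseline_noise_sd > 0) {
      rnorm(n, 0, profile$baseline_noise_sd)
    } else {
      numeric(n)
    }
    sensor_channel(carrier * env + noise, fs, "emg")
  })
}

# Lorenz flow integrated with a fixed-step classical 4th-order Runge-Kutta
# scheme; canonical parameters give a known-positive largest Lyapunov
# exponent (~0.906 per unit flow time), a useful validation target.
lorenz_trajectory <- function(n, dt = 0.01, transient = 2000,
                              init = c(1, 1, 1),
                              sigma = 10, rho = 28, beta = 8 / 3) {
  f <- function(s) {
    c(sigma * (s[2] - s[1]),
      s[1] * (rho - s[3]) - s[2],
      s[1] * s[2] - beta * s[3])
  }
  s <- init
  out <- matrix(0, n, 3)
  total <- transient + n
  for (i in seq_len(total)) {
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > transient) out[i - transient, ] <- s
  }
  out
}

#' Generate three synthetic accelerometer axes
#'
#' Each axis is `periodic_weight * sinusoid + chaotic_weight * chaotic-flow
#' axis + noise_weight * white noise`, each component normalized to unit
#' peak before mixing and the mix scaled to `amplitude`, so the per-axis
#' peak never exceeds `amplitude` and the resultant never exceeds
#' `amplitude * sqrt(3)`.
#'
#' @param profile [complexity_profile].
#' @param duration duration in seconds (`duration * fs >= 1000` samples is
#'   recommended before computing nonlinear features).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return list of three [sensor_channel]s (`acc_x`, `acc_y`, `acc_z`).
#' @export
generate_acc_channels <- function(profile, duration, fs = 100, seed = 1L) {
  if (!inherits(profile, "complexity_profile")) {
    stop_invalid("profile must be a complexity_profile")
  }
  if (duration <= 0 || fs <= 0) stop_invalid("duration and fs must be positive")
  n <- max(2L, round(duration * fs))
  with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    chaos <- if (profile$chaotic_weight > 0) {
      tr <- lorenz_trajectory(n, init = c(1, 1, 1) + runif(3, -0.5, 0.5))
      apply(tr, 2, function(v) {
        v <- v - mean(v)
        v / max(abs(v))
      })
    } else {
      matrix(0, n, 3)
    }
    kinds <- c("acc_x", "acc_y", "acc_z")
    phases <- runif(3, 0, 2 * pi)
    lapply(seq_len(3), function(ax) {
      per <- sin(2 * pi * profile$base_frequency * t + phases[ax])
      noi <- if (profile$noise_weight > 0) {
        w <- rnorm(n)
        w / max(abs(w))
      } else {
        numeric(n)
      }
      mix <- profile$periodic_weight * per +
        profile$chaotic_weight * chaos[, ax] +
        profile$noise_weight * noi
      sensor_channel(profile$amplitude * mix, fs, kinds[ax])
    })
  })
}

# linear blend toward the skill-neutral (intermediate) template, used by
# muscle_effects to plant signal in chosen muscles only
blend_activation <- function(skill_prof, neutral_prof, w) {
  fields <- c("burst_rate", "burst_duration_mean", "burst_amplitude",
              "baseline_noise_sd", "task_duration")
  vals <- lapply(fields, function(f) {
    w * skill_prof[[f]] + (1 - w) * neutral_prof[[f]]
  })
  names(vals) <- fields
  do.call(activation_profile, vals)
}

blend_complexity <- function(skill_prof, neutral_prof, w) {
  mix <- function(f) w * skill_prof[[f]] + (1 - w) * neutral_prof[[f]]
  ww <- c(mix("periodic_weight"), mix("chaotic_weight"), mix("noise_weight"))
  ww <- ww / sum(ww)
  complexity_profile(ww[1], ww[2], ww[3], amplitude = mix("amplitude"),
                     base_frequency = mix("base_frequency"))
}

jitter_activation <- function(prof, sd) {
  f <- exp(rnorm(5, 0, sd))
  activation_profile(prof$burst_rate * f[1],
                     prof$burst_duration_mean * f[2],
                     min(1.5, prof$burst_amplitude * f[3]),
                     prof$baseline_noise_sd * f[4],
                     prof$task_duration * f[5])
}

jitter_complexity <- function(prof, sd) {
  w <- c(prof$periodic_weight, prof$chaotic_weight, prof$noise_weight) *
    exp(rnorm(3, 0, sd))
  w <- w / sum(w)
  complexity_profile(w[1], w[2], w[3], amplitude = prof$amplitude,
                     base_frequency = prof$base_frequency)
}

#' Generate a synthetic cohort of recordings
#'
#' One [recording] per (subject x task x trial x muscle x side).  Each
#' subject gets jittered copies of their skill group's templates; knot
#' tying uses a common task duration across groups (all groups take a
#' similar time on it) while pegboard and robotic suturing inherit the
#' group-specific duration.  The MVC reference is a fixed multiple of the
#' subject's maximum task envelope amplitude per muscle and side.
#'
#' @param config [cohort_config].
#' @return list of [recording] objects.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_invalid("config must be a cohort_config")
  neutral <- config$templates$intermediate
  subjects <- list()
  idx <- 0
  for (skill in SKILL_LEVELS) {
    for (k in seq_len(config$group_sizes[[skill]])) {
      idx <- idx + 1
      subjects[[idx]] <- list(id = sprintf("S%02d", idx), skill = skill)
    }
  }
  recs <- list()
  for (sub in subjects) {
    sseed <- derive_seed(config$seed, "subject", sub$id)
    tmpl <- config$templates[[sub$skill]]
    for (muscle in config$muscles) {
      w <- config$muscle_effects[[muscle]]
      act0 <- blend_activation(tmpl$activation, neutral$activation, w)
      cx0 <- blend_complexity(tmpl$complexity, neutral$complexity, w)
      for (side in config$sides) {
        act <- with_seed(derive_seed(sseed, muscle, side, "jit"),
                         jitter_activation(act0, config$jitter_sd))
        cx <- with_seed(derive_seed(sseed, muscle, side, "jitc"),
                        jitter_complexity(cx0, config$jitter_sd))
        for (task in config$tasks) {
          act_task <- act
          if (task == "knot_tying") {
            # knot tying is similarly demanding in time for all groups
            act_task$task_duration <- neutral$activation$task_duration
          }
          act_task$task_duration <- act_task$task_duration * config$duration_scale
          for (trial in seq_len(config$trials_per_task)) {
            rseed <- derive_seed(sseed, muscle, side, task, trial)
            emg <- generate_emg_channel(act_task, config$emg_fs, rseed)
            base_prof <- act_task
            base_prof$burst_amplitude <- 1e-12
            base_prof$task_duration <- min(config$baseline_duration,
                                           act_task$task_duration)
            baseline <- generate_emg_channel(base_prof, config$emg_fs,
                                             derive_seed(rseed, "base"))
            acc <- generate_acc_channels(cx, act_task$task_duration,
                                         config$acc_fs, derive_seed(rseed, "acc"))
            recs[[length(recs) + 1]] <- recording(
              sub$id, sub$skill, task, trial, muscle, side,
              emg = emg, acc = acc, baseline_emg = baseline, mvc_value = 1)
          }
        }
      }
    }
  }
  # MVC per (subject, muscle, side): fixed multiple of the subject's maximum
  # task envelope amplitude across tasks/trials for that site
  key <- vapply(recs, function(r) paste(r$subject_id, r$muscle, r$side), "")
  for (k in unique(key)) {
    ii <- which(key == k)
    peak <- max(vapply(ii, function(i) {
      max(rms_envelope(recs[[i]]$emg, 6)$samples)
    }, numeric(1)))
    mvc <- config$mvc_multiple * max(peak, .Machine$double.eps)
    for (i in ii) recs[[i]]$mvc_value <- mvc
  }
  recs
}
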