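test_that("EMG generator honours the zero-amplitude and determinism contracts", {
  prof0 <- activation_profile(1, 0.5, 1e-15, 1e-15, 2)
  ch <- generate_emg_channel(prof0, 2000, seed = 1)
  expect_lt(max(abs(ch$samples)), 1e-9)

  prof <- default_skill_templates()$expert$activation
  prof$task_duration <- 3
  a <- generate_emg_channel(prof, 2000, seed = 42)
  b <- generate_emg_channel(prof, 2000, seed = 42)
  expect_identical(a$samples, b$samples)
  c2 <- generate_emg_channel(prof, 2000, seed = 43)
  expect_false(identical(a$samples, c2$samples))
})

test_that("EMG generator rejects invalid rates and durations", {
  prof <- default_skill_templates()$novice$activation
  expect_error(generate_emg_channel(prof, fs = 500), "fs")
  bad <- prof
  bad$task_duration <- -1
  expect_error(generate_emg_channel(bad, 2000), "duration")
  expect_error(activation_profile(1, 1, 2.0, 1, 10), "burst_amplitude")
})

test_that("novice-template EMG yields larger workload than expert-template", {
  tpl <- default_skill_templates()
  cmw_of <- function(prof, seed) {
    prof$task_duration <- 8
    ch <- generate_emg_channel(prof, 1000, seed)
    env <- suppressWarnings(
      preprocess_emg(ch, 2 * max(rms_envelope(ch, 6)$samples)))
    cumulative_muscular_workload(env)
  }
  wins <- sum(vapply(1:100, function(s) {
    cmw_of(tpl$novice$activation, s) > cmw_of(tpl$expert$activation, s + 10000)
  }, logical(1)))
  expect_gte(wins, 95)
})

test_that("accelerometer mixture respects entropy and amplitude contracts", {
  sampen_of <- function(profile, seed) {
    acc <- generate_acc_channels(profile, 10, 100, seed)
    res <- resultant_acceleration(acc[[1]], acc[[2]], acc[[3]])
    as.numeric(sample_entropy(res$samples, 2, 0.2 * sd(res$samples)))
  }
  expect_lte(sampen_of(complexity_profile(1, 0, 0), 3), 0.3)
  expect_gte(sampen_of(complexity_profile(0, 0, 1), 3), 1.5)

  a <- 2.5
  acc <- generate_acc_channels(complexity_profile(0.3, 0.4, 0.3, amplitude = a),
                               10, 100, 5)
  res <- resultant_acceleration(acc[[1]], acc[[2]], acc[[3]])
  expect_lte(max(res$samples), a * sqrt(3) * 1.05)

  expect_error(complexity_profile(0.5, 0.2, 0.2), "sum to 1")
  a1 <- generate_acc_channels(complexity_profile(0.2, 0.4, 0.4), 10, 100, 9)
  a2 <- generate_acc_channels(complexity_profile(0.2, 0.4, 0.4), 10, 100, 9)
  expect_identical(a1[[2]]$samples, a2[[2]]$samples)
})

test_that("cohort enumeration counts and determinism hold", {
  cfg <- cohort_config(group_sizes = c(novice = 1, intermediate = 1, expert = 1),
                       tasks = "pegboard", trials_per_task = 1,
                       muscles = "ECU", sides = "left",
                       duration_scale = 0.2, seed = 2)
  recs <- generate_cohort(cfg)
  expect_length(recs, 3)
  expect_setequal(vapply(recs, `[[`, "", "skill"), skill_levels())

  cfg2 <- cohort_config(group_sizes = c(novice = 2, intermediate = 1, expert = 1),
                        tasks = c("pegboard", "knot_tying"), trials_per_task = 2,
                        muscles = c("ECU", "biceps"), sides = c("left", "right"),
                        duration_scale = 0.15, seed = 7)
  recs2 <- generate_cohort(cfg2)
  expect_length(recs2, 4 * 2 * 2 * 2 * 2)

  recs2b <- generate_cohort(cfg2)
  expect_identical(recs2[[5]]$emg$samples, recs2b[[5]]$emg$samples)
  expect_identical(recs2[[5]]$mvc_value, recs2b[[5]]$mvc_value)

  expect_error(cohort_config(group_sizes = c(novice = 0, intermediate = 1,
                                             expert = 1)),
               "non-empty")
})

test_that("dataset serialization round-trips every field and sample exactly", {
  cfg <- cohort_config(group_sizes = c(novice = 1, intermediate = 1, expert = 1),
                       tasks = "knot_tying", trials_per_task = 1,
                       muscles = "TE", sides = "right",
                       duration_scale = 0.15, seed = 4)
  recs <- generate_cohort(cfg)
  dd <- withr::local_tempdir()
  write_dataset(recs, dd)
  back <- read_dataset(dd)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$subject_id, recs[[i]]$subject_id)
    expect_identical(back[[i]]$skill, recs[[i]]$skill)
    expect_identical(back[[i]]$trial, recs[[i]]$trial)
    expect_identical(back[[i]]$emg$samples, recs[[i]]$emg$samples)
    expect_identical(back[[i]]$baseline_emg$samples, recs[[i]]$baseline_emg$samples)
    expect_identical(back[[i]]$acc[[3]]$samples, recs[[i]]$acc[[3]]$samples)
    expect_identical(back[[i]]$mvc_value, recs[[i]]$mvc_value)
  }
})

test_that("a manifest pointing at a deleted file raises a corrupt-dataset error", {
  cfg <- cohort_config(group_sizes = c(novice = 1, intermediate = 1, expert = 1),
                       tasks = "pegboard", trials_per_task = 1,
                       muscles = "FCU", sides = "left",
                       duration_scale = 0.15, seed = 6)
  dd <- withr::local_tempdir()
  write_dataset(generate_cohort(cfg), dd)
  victim <- list.files(dd, pattern = "_acc\\.csv$", full.names = TRUE)[1]
  unlink(victim)
  expect_error(read_dataset(dd), "missing channel file")
  expect_error(read_dataset(dd), basename(victim))
})

test_that("an empty cohort writes a valid zero-entry dataset", {
  dd <- withr::local_tempdir()
  write_dataset(list(), dd)
  expect_true(file.exists(file.path(dd, "manifest.json")))
  expect_length(read_dataset(dd), 0)
})

test_that("synthetic groups separate in the reported directions", {
  cfg <- cohort_config(group_sizes = c(novice = 20, intermediate = 20, expert = 20),
                       tasks = "pegboard", trials_per_task = 1,
                       muscles = "ECU", sides = "left",
                       duration_scale = 0.4, seed = 10)
  recs <- generate_cohort(cfg)
  tab <- suppressWarnings(build_feature_table(recs))
  by_skill <- split(tab, tab$skill)
  one_sided <- function(feature, hi, lo) {
    stats::wilcox.test(by_skill[[hi]][[feature]], by_skill[[lo]][[feature]],
                       alternative = "greater")$p.value
  }
  # workload: novice > intermediate > expert
  expect_lt(one_sided("CMW", "novice", "intermediate"), 0.05)
  expect_lt(one_sided("CMW", "intermediate", "expert"), 0.05)
  # pegboard completion/activation time: novice longest
  expect_lt(one_sided("TotalTime", "novice", "expert"), 0.05)
  # movement complexity: novice most entropic
  expect_lt(one_sided("MeanMSE", "novice", "expert"), 0.05)
})
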