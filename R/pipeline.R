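#' Pipeline configuration
#'
#' Bundles every stage's parameters with one global seed.  Stage seeds are
#' derived deterministically from the global seed and the stage name, so a
#' stage re-run in isolation reproduces the full-pipeline run exactly.
#'
#' @param cohort [cohort_config()].
#' @param nonlinear [nonlinear_params()].
#' @param rho_threshold CFS correlation threshold.
#' @param n_keep RFE target feature count.
#' @param split [split_spec()].
#' @param muscle_sets muscle sets to evaluate (defaults to the six
#'   singletons).
#' @param models classifiers to run.
#' @param envelope_store_fs rate (Hz) at which envelope artifacts are
#'   stored for inspection; the 5 Hz envelope is heavily oversampled at
#'   the native rate so 200 Hz loses nothing visible.
#' @param seed global integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            nonlinear = nonlinear_params(),
                            rho_threshold = 0.9, n_keep = 10,
                            split = split_spec(),
                            muscle_sets = as.list(muscle_names()),
                            models = c("rf", "svm", "nb"),
                            envelope_store_fs = 200,
                            seed = 1L) {
  structure(list(cohort = cohort, nonlinear = nonlinear,
                 rho_threshold = rho_threshold, n_keep = n_keep,
                 split = split, muscle_sets = muscle_sets, models = models,
                 envelope_store_fs = envelope_store_fs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("simulate", "preprocess", "features", "select",
                     "train", "report")

stage_dir <- function(out_dir, stage) file.path(out_dir, stage)

stage_done_file <- function(out_dir, stage) {
  file.path(stage_dir(out_dir, stage), "provenance.json")
}

require_stage <- function(out_dir, stage) {
  if (!file.exists(stage_done_file(out_dir, stage))) {
    stop_invalid("stage '%s' has not been run in '%s'; run it first",
                 stage, out_dir)
  }
}

write_provenance <- function(out_dir, stage, config, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, global_seed = config$seed,
           stage_seed = derive_seed(config$seed, stage)), extra),
    stage_done_file(out_dir, stage), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate + write the dataset), `preprocess`
#' (store decimated MVC-normalized envelopes for inspection), `features`
#' (full feature table from the raw dataset at native rates), `select`
#' (CFS + RFE reduction), `train` (per-muscle-set model evaluation),
#' `report` (summary tables and ROC points).  Each stage writes a
#' provenance file; a stage whose upstream artifacts are missing stops
#' with an error naming the missing stage.
#'
#' @param stage stage name.
#' @param config [pipeline_config()].
#' @param out_dir output directory.
#' @return path of the stage directory, invisibly.
#' @export
run_stage <- function(stage, config, out_dir) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  sdir <- stage_dir(out_dir, stage)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = {
      cfg <- config$cohort
      cfg$seed <- derive_seed(config$seed, "simulate")
      recs <- generate_cohort(cfg)
      write_dataset(recs, file.path(sdir, "dataset"))
      write_provenance(out_dir, stage, config,
                       list(n_recordings = length(recs)))
    },
    preprocess = {
      require_stage(out_dir, "simulate")
      recs <- read_dataset(file.path(stage_dir(out_dir, "simulate"), "dataset"))
      edir <- file.path(sdir, "envelopes")
      dir.create(edir, showWarnings = FALSE)
      for (rec in recs) {
        env <- preprocess_emg(rec$emg, rec$mvc_value)
        step <- max(1L, round(env$fs / config$envelope_store_fs))
        idx <- seq(1, length(env$samples), by = step)
        write_channel_csv(file.path(edir, paste0(recording_id(rec), "_env.csv")),
                          c("time_s", "envelope_mvc"),
                          list((idx - 1) / env$fs, env$samples[idx]))
      }
      write_provenance(out_dir, stage, config,
                       list(n_recordings = length(recs),
                            store_fs = config$envelope_store_fs))
    },
    features = {
      require_stage(out_dir, "simulate")
      require_stage(out_dir, "preprocess")
      recs <- read_dataset(file.path(stage_dir(out_dir, "simulate"), "dataset"))
      tab <- build_feature_table(recs, config$nonlinear, level = "trial")
      write_feature_table(tab, file.path(sdir, "feature_table.tsv"))
      subj <- aggregate_subject_level(tab)
      write_feature_table(subj, file.path(sdir, "feature_table_subject.tsv"))
      write_provenance(out_dir, stage, config, list(n_rows = nrow(tab)))
    },
    select = {
      require_stage(out_dir, "features")
      tab <- read_feature_table(file.path(stage_dir(out_dir, "features"),
                                          "feature_table.tsv"))
      red <- reduce_dimension(tab, "cfs_rfe", n_keep = config$n_keep,
                              rho_threshold = config$rho_threshold,
                              seed = derive_seed(config$seed, "select"))
      write_feature_table(red, file.path(sdir, "selected_table.tsv"))
      write_selection_report(attr(red, "selection"),
                             file.path(sdir, "feature_priority.tsv"))
      write_provenance(out_dir, stage, config,
                       list(n_kept = length(feature_columns(red))))
    },
    train = {
      require_stage(out_dir, "features")
      tab <- read_feature_table(file.path(stage_dir(out_dir, "features"),
                                          "feature_table.tsv"))
      spec <- config$split
      spec$seed <- derive_seed(config$seed, "split")
      report <- evaluate_muscle_sets(tab, config$muscle_sets, spec,
                                     seed = derive_seed(config$seed, "train"),
                                     models = config$models)
      met <- report$metrics
      met[-(1:2)] <- lapply(met[-(1:2)], format_full)
      con <- file(file.path(sdir, "metrics.tsv"), "wb")
      writeLines(c(paste(names(met), collapse = "\t"),
                   do.call(paste, c(met, list(sep = "\t")))), con)
      close(con)
      saveRDS_path <- file.path(sdir, "report.rds")
      saveRDS(report, saveRDS_path)  # runtime artifact only
      write_provenance(out_dir, stage, config, list(n_runs = nrow(report$metrics)))
    },
    report = {
      require_stage(out_dir, "train")
      require_stage(out_dir, "features")
      report <- readRDS(file.path(stage_dir(out_dir, "train"), "report.rds"))
      rdir <- file.path(sdir, "roc")
      dir.create(rdir, showWarnings = FALSE)
      for (nm in names(report$details)) {
        roc <- report$details[[nm]]$roc
        for (lv in names(roc)) {
          write_channel_csv(file.path(rdir, paste0(gsub("[^A-Za-z0-9]+", "_", nm),
                                                   "_", lv, ".csv")),
                            c("fpr", "tpr"),
                            list(roc[[lv]]$fpr, roc[[lv]]$tpr))
        }
      }
      tab <- read_feature_table(file.path(stage_dir(out_dir, "features"),
                                          "feature_table.tsv"))
      summ <- summarize_group_differences(tab)
      write_feature_table(summ$summary, file.path(sdir, "group_summary.tsv"))
      file.copy(file.path(stage_dir(out_dir, "train"), "metrics.tsv"),
                file.path(sdir, "metrics.tsv"), overwrite = TRUE)
      write_provenance(out_dir, stage, config, list())
    })
  invisible(sdir)
}

#' Run the whole pipeline
#' @param config [pipeline_config()].
#' @param out_dir output directory.
#' @param stages stages to run, in order.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = PIPELINE_STAGES) {
  for (s in stages) run_stage(s, config, out_dir)
  invisible(out_dir)
}

#' Descriptive per-group feature summary
#'
#' Mean, SD and n per (skill, task) for every feature, plus direction
#' flags comparing novice vs expert group means when both are present.
#'
#' @param table labeled feature table.
#' @return list with `summary` data.frame and `directions` data.frame
#'   (feature, task, direction in `novice > expert` / `novice < expert`).
#' @export
summarize_group_differences <- function(table) {
  feats <- feature_columns(table)
  keep <- feats[vapply(feats, function(f) any(is.finite(table[[f]])), logical(1))]
  dropped <- setdiff(feats, keep)
  if (length(dropped) > 0) {
    message("excluded all-missing feature(s): ", paste(dropped, collapse = ", "))
  }
  rows <- list()
  for (f in keep) {
    agg <- aggregate(table[[f]], list(skill = table$skill, task = table$task),
                     function(v) c(mean = mean(v, na.rm = TRUE),
                                   sd = sd(v, na.rm = TRUE),
                                   n = sum(is.finite(v))))
    rows[[f]] <- data.frame(feature = f, skill = agg$skill, task = agg$task,
                            mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                            n = agg$x[, "n"])
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  directions <- NULL
  if (all(c("novice", "expert") %in% unique(table$skill))) {
    dl <- list()
    for (f in keep) {
      for (tk in unique(summary$task)) {
        m <- summary[summary$feature == f & summary$task == tk, ]
        nv <- m$mean[m$skill == "novice"]
        ex <- m$mean[m$skill == "expert"]
        if (length(nv) == 1 && length(ex) == 1 && is.finite(nv) && is.finite(ex)) {
          dl[[length(dl) + 1]] <- data.frame(
            feature = f, task = tk,
            direction = if (nv > ex) "novice > expert" else "novice < expert")
        }
      }
    }
    directions <- do.call(rbind, dl)
  }
  list(summary = summary, directions = directions)
}
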