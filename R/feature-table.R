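#' Build the feature table for a cohort
#'
#' At `level = "trial"` every row is one recording unit (subject, task,
#' trial, muscle, side) with the six EMG features (`CMW`, `AWS`,
#' `TotalTime`, `RMS`, `Range`, `DominantFreq`) and the nonlinear
#' accelerometer features.  At `level = "subject"` trials are averaged
#' within (subject, task, muscle, side) and the accelerometer aggregates
#' are renamed to their conventional reporting names (`Mean_Apen`,
#' `Mean_MSE`, `Mean_Sample_Entropy`, `Var_MSE`, `Mean_Wolf_Lye`,
#' `Mean_Short_Lye`, `Mean_Long_Lye`, `Mean_Correlation_Dimension`,
#' `Mean_Generalized_Hurst_Exp`).
#'
#' @param recordings list of [recording]s.
#' @param params [nonlinear_params()].
#' @param level `"trial"` or `"subject"`.
#' @param progress print a progress message every 100 recordings.
#' @return data.frame with key columns `subject`, `skill`, `task`, `trial`
#'   (trial level only), `muscle`, `side` followed by feature columns.
#' @export
build_feature_table <- function(recordings, params = nonlinear_params(),
                                level = c("trial", "subject"),
                                progress = FALSE) {
  level <- match.arg(level)
  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    feats <- c(emg_feature_vector(rec), acc_feature_vector(rec, params))
    rows[[i]] <- data.frame(subject = rec$subject_id, skill = rec$skill,
                            task = rec$task, trial = rec$trial,
                            muscle = rec$muscle, side = rec$side,
                            as.list(feats), check.names = FALSE)
    if (progress && i %% 100 == 0) {
      message(sprintf("features: %d / %d recordings", i, length(recordings)))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (level == "trial") return(tab)
  aggregate_subject_level(tab)
}

ACC_SUBJECT_NAMES <- c(
  ApEn = "Mean_Apen", MeanMSE = "Mean_MSE", SampEn = "Mean_Sample_Entropy",
  VarMSE = "Var_MSE", WolfLyE = "Mean_Wolf_Lye", ShortLyE = "Mean_Short_Lye",
  LongLyE = "Mean_Long_Lye", CorrDim = "Mean_Correlation_Dimension",
  HurstExp = "Mean_Generalized_Hurst_Exp", RosensteinLyE = "Mean_Rosenstein_Lye")

aggregate_subject_level <- function(tab) {
  keys <- c("subject", "skill", "task", "muscle", "side")
  feat_cols <- setdiff(names(tab), c(keys, "trial"))
  agg <- aggregate(tab[feat_cols], tab[keys], function(v) mean(v, na.rm = TRUE))
  ren <- names(agg)
  hit <- ren %in% names(ACC_SUBJECT_NAMES)
  ren[hit] <- ACC_SUBJECT_NAMES[ren[hit]]
  names(agg) <- ren
  agg
}

#' Columns of a feature table that hold features
#' @param table feature table data.frame.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject", "skill", "task", "trial", "muscle", "side"))
}

#' Reshape a feature table for a muscle set
#'
#' Restricts the table to the given muscles and concatenates each
#' (muscle, side) unit's features into one wide row per
#' (subject, task, trial), with columns named `<muscle>_<side>_<feature>`.
#' This is how single-muscle and muscle-combination classification
#' datasets are formed.
#'
#' @param table trial-level feature table.
#' @param muscles subset of `muscle_names()`.
#' @return wide data.frame with `subject`, `skill`, `task`, `trial` keys.
#' @export
muscle_subset_table <- function(table, muscles) {
  bad <- setdiff(muscles, MUSCLES)
  if (length(bad) > 0) stop_invalid("unknown muscle(s): %s", paste(bad, collapse = ", "))
  sub <- table[table$muscle %in% muscles, , drop = FALSE]
  if (nrow(sub) == 0) stop_invalid("no rows for muscles %s", paste(muscles, collapse = ", "))
  feat_cols <- feature_columns(sub)
  has_trial <- "trial" %in% names(sub)
  keys <- if (has_trial) c("subject", "skill", "task", "trial") else
    c("subject", "skill", "task")
  sub$unit <- paste(sub$muscle, sub$side, sep = "_")
  wide <- NULL
  for (u in sort(unique(sub$unit))) {
    blk <- sub[sub$unit == u, c(keys, feat_cols), drop = FALSE]
    names(blk)[-seq_along(keys)] <- paste(u, feat_cols, sep = "_")
    wide <- if (is.null(wide)) blk else merge(wide, blk, by = keys, sort = TRUE)
  }
  wide[do.call(order, wide[keys]), , drop = FALSE]
}

#' Write / read a feature table as delimited text
#' @param table feature table.
#' @param path file path.
#' @return the path (write) or the table (read).
#' @export
#' @rdname feature-table-io
write_feature_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(out[num], format_full)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               do.call(paste, c(out, list(sep = "\t")))), con)
  invisible(path)
}

#' @export
#' @rdname feature-table-io
read_feature_table <- function(path) {
  tab <- read.csv(path, sep = "\t", check.names = FALSE)
  if ("trial" %in% names(tab)) tab$trial <- as.integer(tab$trial)
  tab
}
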