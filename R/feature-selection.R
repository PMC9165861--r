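#' Pairwise Pearson correlation matrix of feature columns
#'
#' Zero-variance features get `NA` rows/columns and are reported in the
#' `"undefined_features"` attribute rather than failing silently.
#'
#' @param table feature table (only feature columns are used).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation_matrix <- function(table) {
  feats <- table[feature_columns(table)]
  if (nrow(feats) < 2) stop_invalid("need >= 2 rows to correlate features")
  sds <- vapply(feats, function(v) sd(v, na.rm = TRUE), numeric(1))
  bad <- names(sds)[!is.finite(sds) | sds == 0]
  cm <- suppressWarnings(cor(as.matrix(feats), use = "pairwise.complete.obs"))
  diag(cm) <- 1
  cm[bad, ] <- NA_real_
  cm[, bad] <- NA_real_
  diag(cm)[] <- 1
  attr(cm, "undefined_features") <- bad
  cm
}

# association of each feature with the ordered skill label: Pearson
# correlation against the integer-coded novice < intermediate < expert axis
label_association <- function(table) {
  y <- as.numeric(factor(table$skill, levels = SKILL_LEVELS))
  feats <- table[feature_columns(table)]
  vapply(feats, function(v) {
    if (sd(v, na.rm = TRUE) == 0) return(0)
    abs(suppressWarnings(cor(v, y, use = "complete.obs")))
  }, numeric(1))
}

#' Correlation-based filter feature selection
#'
#' For every feature pair with `|rho| >= rho_threshold` (processed in
#' decreasing `|rho|` order), drops the member with the weaker absolute
#' association to the skill label (ties drop the later column).  The
#' default threshold of 0.9 is high enough that only genuinely redundant
#' features - such as the strongly inter-correlated entropy family - are
#' filtered.
#'
#' @param table labeled feature table.
#' @param rho_threshold correlation magnitude threshold in (0, 1\].
#' @return list with `kept_features`, `dropped_pairs` (kept, dropped,
#'   abs_rho), and the `correlation_matrix`.
#' @export
cfs_filter <- function(table, rho_threshold = 0.9) {
  if (rho_threshold <= 0 || rho_threshold > 1) {
    stop_invalid("rho_threshold must lie in (0, 1]")
  }
  cm <- pearson_correlation_matrix(table)
  assoc <- label_association(table)
  feats <- colnames(cm)
  alive <- setNames(rep(TRUE, length(feats)), feats)
  pairs <- which(upper.tri(cm) & abs(cm) >= rho_threshold &
                   is.finite(cm), arr.ind = TRUE)
  dropped <- list()
  if (nrow(pairs) > 0) {
    ord <- order(-abs(cm[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      a <- feats[pairs[p, 1]]
      b <- feats[pairs[p, 2]]
      if (!alive[a] || !alive[b]) next
      # keep the member more associated with the label; tie -> later column
      drop <- if (assoc[a] > assoc[b]) b else if (assoc[b] > assoc[a]) a else b
      keep <- if (drop == a) b else a
      alive[drop] <- FALSE
      dropped[[length(dropped) + 1]] <-
        data.frame(kept = keep, dropped = drop,
                   abs_rho = abs(cm[pairs[p, 1], pairs[p, 2]]))
    }
  }
  list(kept_features = feats[alive],
       dropped_pairs = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(kept = character(), dropped = character(),
                    abs_rho = numeric()),
       correlation_matrix = cm)
}

#' Recursive feature elimination with a random-forest ranker
#'
#' Fits a random forest, removes the feature with the lowest importance,
#' and repeats until `n_keep` features remain.  Ranks record the
#' elimination order (rank 1 = survived to the final set); weights are the
#' final fit's importances normalized to sum to 1.
#'
#' @param table labeled feature table.
#' @param n_keep number of features to keep.
#' @param seed integer seed (forest fits are seeded per iteration).
#' @param ntree trees per forest fit.
#' @return list with `kept_features` (ordered by final importance,
#'   descending), `ranks`, `weights`.
#' @export
rfe_rank <- function(table, n_keep = 10, seed = 1L, ntree = 100) {
  feats <- feature_columns(table)
  if (n_keep < 1) stop_invalid("n_keep must be >= 1")
  if (n_keep > length(feats)) {
    stop_invalid("n_keep = %d exceeds the %d available features",
                 n_keep, length(feats))
  }
  y <- factor(table$skill, levels = SKILL_LEVELS)
  y <- droplevels(y)
  x_all <- impute_median(table[feats])
  current <- feats
  ranks <- setNames(rep(1L, length(feats)), feats)
  iter <- 0L
  imp <- NULL
  repeat {
    iter <- iter + 1L
    fit <- with_seed(derive_seed(seed, "rfe", iter), {
      randomForest::randomForest(x_all[current], y, ntree = ntree)
    })
    imp_m <- randomForest::importance(fit)
    imp <- setNames(imp_m[, 1], rownames(imp_m))
    if (length(current) == n_keep) break
    worst <- names(which.min(imp))
    ranks[worst] <- length(current)  # removed while this many were alive
    current <- setdiff(current, worst)
  }
  w <- imp / sum(imp)
  ord <- order(-w)
  list(kept_features = names(w)[ord],
       ranks = ranks,
       weights = w[ord])
}

impute_median <- function(df) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (anyNA(v)) {
      med <- median(v, na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      v[is.na(v)] <- med
      df[[j]] <- v
    }
  }
  df
}

#' Reduce a feature table's dimensionality
#'
#' Applies the correlation filter, then recursive feature elimination down
#' to `n_keep` features (10 by default), and projects the table onto the
#' kept features.  Applying the same reduction twice is idempotent.
#'
#' @param table labeled feature table.
#' @param method `"cfs_rfe"`, `"cfs"`, `"rfe"`, or `"none"`.
#' @param n_keep RFE target size.
#' @param rho_threshold CFS threshold.
#' @param seed integer seed.
#' @return reduced table, with the selection details in attribute
#'   `"selection"`.
#' @export
reduce_dimension <- function(table, method = c("cfs_rfe", "cfs", "rfe", "none"),
                             n_keep = 10, rho_threshold = 0.9, seed = 1L) {
  method <- match.arg(method)
  key_cols <- intersect(c("subject", "skill", "task", "trial", "muscle", "side"),
                        names(table))
  sel <- list(kept_features = feature_columns(table))
  if (method %in% c("cfs_rfe", "cfs")) {
    sel_cfs <- cfs_filter(table, rho_threshold)
    table <- table[c(key_cols, sel_cfs$kept_features)]
    sel <- sel_cfs
  }
  if (method %in% c("cfs_rfe", "rfe")) {
    n_keep_eff <- min(n_keep, length(feature_columns(table)))
    sel_rfe <- rfe_rank(table, n_keep_eff, seed)
    table <- table[c(key_cols, sel_rfe$kept_features)]
    sel$ranks <- sel_rfe$ranks
    sel$weights <- sel_rfe$weights
    sel$kept_features <- sel_rfe$kept_features
  }
  attr(table, "selection") <- sel
  table
}

#' Write a feature-priority report (feature, rank, weight)
#' @param selection selection list from [rfe_rank()] / [reduce_dimension()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  w <- selection$weights
  df <- data.frame(feature = names(w),
                   rank = selection$ranks[names(w)],
                   weight = format_full(unname(w)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(df, list(sep = "\t")))), con)
  invisible(path)
}
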