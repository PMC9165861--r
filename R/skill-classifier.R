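#' Train/test split specification
#'
#' @param train_fraction fraction of data used for training (0.7 by the
#'   study protocol).
#' @param grouping `"subject"` keeps all rows of a subject in one
#'   partition (no leakage across a subject's trials); `"row"` splits
#'   individual rows.
#' @param seed integer seed.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, grouping = c("subject", "row"),
                       seed = 1L) {
  grouping <- match.arg(grouping)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("train_fraction must lie in (0, 1)")
  }
  structure(list(train_fraction = train_fraction, grouping = grouping,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Stratified train/test split
#'
#' Stratifies by skill label; with subject grouping, subjects (not rows)
#' are allocated within each skill stratum, so the train and test subject
#' sets are disjoint.  Deterministic per seed.
#'
#' @param table labeled feature table.
#' @param spec [split_spec()].
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(table, spec = split_spec()) {
  y <- factor(table$skill, levels = SKILL_LEVELS)
  y <- droplevels(y)
  counts <- table(y)
  if (any(counts < 2)) {
    stop_invalid("class '%s' has fewer than 2 rows",
                 names(counts)[which(counts < 2)[1]])
  }
  train_idx <- with_seed(spec$seed, {
    idx <- integer(0)
    for (lev in levels(y)) {
      rows <- which(y == lev)
      if (spec$grouping == "subject") {
        subs <- unique(table$subject[rows])
        n_tr <- max(1, min(length(subs) - 1,
                           round(spec$train_fraction * length(subs))))
        tr_subs <- sample(subs, n_tr)
        idx <- c(idx, rows[table$subject[rows] %in% tr_subs])
      } else {
        n_tr <- max(1, min(length(rows) - 1,
                           round(spec$train_fraction * length(rows))))
        idx <- c(idx, sample(rows, n_tr))
      }
    }
    sort(idx)
  })
  list(train = table[train_idx, , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}

#' Train the three skill classifiers
#'
#' Fits a 100-tree random forest, a Gaussian naive Bayes classifier, and a
#' radial-basis-kernel SVM on the feature columns.  Features are
#' median-imputed and standardized with statistics fitted on the training
#' data only; the same transform is applied at prediction time.
#'
#' @param train_table labeled training table.
#' @param seed integer seed.
#' @param ntree random-forest size.
#' @param models subset of `c("rf", "svm", "nb")`.
#' @return object of class `skill_models`.
#' @export
train_models <- function(train_table, seed = 1L, ntree = 100,
                         models = c("rf", "svm", "nb")) {
  feats <- feature_columns(train_table)
  y <- factor(train_table$skill, levels = SKILL_LEVELS)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop_invalid("training data contains a single class")
  x <- impute_median(train_table[feats])
  centers <- vapply(x, mean, numeric(1))
  sds <- vapply(x, sd, numeric(1))
  sds[!is.finite(sds) | sds == 0] <- 1
  xs <- as.data.frame(scale(x, center = centers, scale = sds))
  medians <- vapply(x, median, numeric(1))
  fits <- list()
  if ("rf" %in% models) {
    fits$rf <- with_seed(derive_seed(seed, "rf"),
                         randomForest::randomForest(xs, y, ntree = ntree))
  }
  if ("svm" %in% models) {
    fits$svm <- with_seed(derive_seed(seed, "svm"),
                          e1071::svm(xs, y, kernel = "radial",
                                     probability = TRUE))
  }
  if ("nb" %in% models) {
    fits$nb <- e1071::naiveBayes(xs, y)
  }
  structure(list(fits = fits, features = feats, centers = centers,
                 sds = sds, medians = medians, levels = levels(y)),
            class = "skill_models")
}

scale_new <- function(object, table) {
  x <- table[object$features]
  for (j in seq_along(x)) {
    v <- x[[j]]
    v[is.na(v)] <- object$medians[[j]]
    x[[j]] <- (v - object$centers[[j]]) / object$sds[[j]]
  }
  x
}

#' Predict skill labels and class scores
#'
#' @param object `skill_models` fit.
#' @param table feature table to score.
#' @param model one of `"rf"`, `"svm"`, `"nb"`.
#' @param ... unused.
#' @return list with `class` (factor) and `prob` (matrix of class scores).
#' @export
predict.skill_models <- function(object, table, model = "rf", ...) {
  fit <- object$fits[[model]]
  if (is.null(fit)) stop_invalid("model '%s' was not trained", model)
  xs <- scale_new(object, table)
  if (model == "rf") {
    prob <- predict(fit, xs, type = "prob")
    cls <- predict(fit, xs)
  } else if (model == "svm") {
    pr <- predict(fit, xs, probability = TRUE)
    prob <- attr(pr, "probabilities")[, object$levels, drop = FALSE]
    cls <- pr
  } else {
    prob <- predict(fit, xs, type = "raw")
    cls <- factor(object$levels[max.col(prob, ties.method = "first")],
                  levels = object$levels)
  }
  list(class = factor(as.character(cls), levels = object$levels),
       prob = prob[, object$levels, drop = FALSE])
}

#' Confusion matrix and classification metrics
#'
#' Builds the 3x3 confusion matrix and, for each class taken one-vs-rest,
#' accuracy `(TP+TN)/(TP+FP+TN+FN)`, recall `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and
#' `F1 = 2 * recall * precision / (recall + precision)`.  Zero-denominator
#' metrics are `NA` for that class and excluded from the macro average.
#' Overall accuracy is the multi-class trace accuracy.
#'
#' @param y_true,y_pred factors or characters over the skill labels.
#' @return list with `confusion`, `per_class` (data.frame), and `macro`
#'   (named vector: accuracy, precision, recall, specificity, f1).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_invalid("length mismatch")
  levs <- intersect(SKILL_LEVELS, unique(c(as.character(y_true),
                                           as.character(y_pred))))
  y_true <- factor(as.character(y_true), levels = levs)
  y_pred <- factor(as.character(y_pred), levels = levs)
  cm <- table(true = y_true, predicted = y_pred)
  n <- sum(cm)
  per <- lapply(levs, function(lv) {
    tp <- cm[lv, lv]
    fn <- sum(cm[lv, ]) - tp
    fp <- sum(cm[, lv]) - tp
    tn <- n - tp - fn - fp
    safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
    prec <- safe_div(tp, tp + fp)
    rec <- safe_div(tp, tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
      2 * rec * prec / (rec + prec)
    data.frame(class = lv, TP = tp, FP = fp, FN = fn, TN = tn,
               accuracy = (tp + tn) / n, precision = prec, recall = rec,
               specificity = safe_div(tn, tn + fp), f1 = f1)
  })
  per <- do.call(rbind, per)
  macro <- c(accuracy = sum(diag(cm)) / n,
             precision = mean(per$precision, na.rm = TRUE),
             recall = mean(per$recall, na.rm = TRUE),
             specificity = mean(per$specificity, na.rm = TRUE),
             f1 = mean(per$f1, na.rm = TRUE))
  list(confusion = cm, per_class = per, macro = macro)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps thresholds over the class score, collecting
#' (FPR, TPR) points from (0,0) to (1,1); AUC by the trapezoid rule.
#'
#' @param scores matrix of per-class scores (columns named by class).
#' @param y_true true labels.
#' @return named list per class: `fpr`, `tpr`, `auc`; classes absent from
#'   `y_true` are returned as `NULL` with a warning.
#' @export
roc_one_vs_rest <- function(scores, y_true) {
  y_true <- as.character(y_true)
  out <- list()
  for (lv in colnames(scores)) {
    pos <- y_true == lv
    if (!any(pos) || all(pos)) {
      warning(sprintf("class '%s' absent from one side of y_true; ROC undefined", lv))
      out[[lv]] <- NULL
      next
    }
    s <- scores[, lv]
    ord <- order(s, decreasing = TRUE)
    pos_o <- pos[ord]
    s_o <- s[ord]
    tp <- cumsum(pos_o)
    fp <- cumsum(!pos_o)
    # one ROC point per distinct threshold
    keep <- c(diff(s_o) != 0, TRUE)
    tpr <- c(0, tp[keep] / sum(pos))
    fpr <- c(0, fp[keep] / sum(!pos))
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    out[[lv]] <- list(fpr = fpr, tpr = tpr, auc = auc)
  }
  out
}

#' Evaluate classifiers over muscle sets
#'
#' For each muscle set, builds the wide per-(subject, task, trial) dataset
#' from that set's sensors, makes one stratified split, trains the three
#' classifiers, and reports test metrics plus one-vs-rest ROC per class.
#'
#' @param table trial-level feature table for the whole cohort.
#' @param muscle_sets list of character vectors of muscle names.
#' @param spec [split_spec()].
#' @param seed integer seed for model training.
#' @param models classifiers to run.
#' @return object of class `skill_model_report`: `metrics` data.frame
#'   (muscle_set, model, accuracy, precision, recall, specificity, f1) and
#'   `details` (per run: confusion, per-class metrics, ROC).
#' @export
evaluate_muscle_sets <- function(table, muscle_sets, spec = split_spec(),
                                 seed = 1L, models = c("rf", "svm", "nb")) {
  rows <- list()
  details <- list()
  for (ms in muscle_sets) {
    set_name <- paste(ms, collapse = "+")
    wide <- muscle_subset_table(table, ms)
    parts <- split_train_test(wide, spec)
    fit <- train_models(parts$train, seed = derive_seed(seed, set_name),
                        models = models)
    for (mod in models) {
      pred <- predict(fit, parts$test, model = mod)
      met <- confusion_metrics(parts$test$skill, pred$class)
      roc <- suppressWarnings(roc_one_vs_rest(pred$prob, parts$test$skill))
      rows[[length(rows) + 1]] <- data.frame(
        muscle_set = set_name, model = mod,
        accuracy = met$macro[["accuracy"]], precision = met$macro[["precision"]],
        recall = met$macro[["recall"]], specificity = met$macro[["specificity"]],
        f1 = met$macro[["f1"]])
      details[[paste(set_name, mod, sep = ":")]] <-
        list(confusion = met$confusion, per_class = met$per_class, roc = roc)
    }
  }
  structure(list(metrics = do.call(rbind, rows), details = details,
                 spec = spec, seed = seed),
            class = "skill_model_report")
}

#' @export
print.skill_model_report <- function(x, ...) {
  cat("Skill classification report (test-set macro metrics)\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}
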