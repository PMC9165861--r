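make_sep_table <- function(n_per_class = 40, gap = 6, seed = 1, subjects = 10) {
  set.seed(seed)
  skills <- rep(skill_levels(), each = n_per_class)
  mu <- (as.numeric(factor(skills, levels = skill_levels())) - 1) * gap
  subj <- sprintf("%s%02d", substr(skills, 1, 1),
                  rep_len(seq_len(subjects), length(skills)))
  data.frame(subject = subj, skill = skills,
             f1 = rnorm(length(skills), mu),
             f2 = rnorm(length(skills), -mu / 2))
}

test_that("stratified splitting preserves proportions and is deterministic", {
  tab <- make_sep_table(40, seed = 2)
  sp <- split_spec(grouping = "row", seed = 9)
  parts <- split_train_test(tab, sp)
  expect_equal(nrow(parts$train), 84)  # 0.7 * 120
  expect_equal(nrow(parts$test), 36)
  for (lv in skill_levels()) {
    expect_equal(sum(parts$train$skill == lv), 28)
  }
  parts2 <- split_train_test(tab, sp)
  expect_identical(parts$train, parts2$train)
  expect_error(split_train_test(tab[c(1, 41, 42, 81, 82), ], sp),
               "fewer than 2")
})

test_that("subject-level splitting keeps subjects on one side only", {
  tab <- make_fake_trial_table(n_subj_per_class = 6, trials = 3,
                               muscles = "ECU", seed = 3)
  wide <- muscle_subset_table(tab, "ECU")
  parts <- split_train_test(wide, split_spec(grouping = "subject", seed = 5))
  expect_length(intersect(unique(parts$train$subject),
                          unique(parts$test$subject)), 0)
  expect_setequal(unique(parts$train$skill), skill_levels())
})

test_that("all three models learn separable classes and shuffle to chance", {
  tab <- make_sep_table(40, gap = 6, seed = 4)
  fit <- train_models(tab, seed = 1)
  for (mod in c("rf", "svm", "nb")) {
    pred <- predict(fit, tab, model = mod)
    expect_gte(mean(pred$class == tab$skill), 0.95)
  }
  # label shuffling collapses test accuracy to the 3-class chance band
  accs <- vapply(1:5, function(s) {
    t2 <- tab
    set.seed(s)
    t2$skill <- sample(t2$skill)
    parts <- split_train_test(t2, split_spec(grouping = "row", seed = s))
    f <- train_models(parts$train, seed = s)
    mean(predict(f, parts$test, "rf")$class == parts$test$skill)
  }, numeric(1))
  expect_equal(mean(accs), 1 / 3, tolerance = 0.1 / (1 / 3))
  expect_error(train_models(tab[tab$skill == "novice", ]), "single class")
  # determinism of the fitted ensemble
  f1 <- train_models(tab, seed = 7)
  f2 <- train_models(tab, seed = 7)
  expect_identical(predict(f1, tab, "rf")$class, predict(f2, tab, "rf")$class)
})

test_that("confusion metrics reproduce hand-computed counts and formulas", {
  perfect <- confusion_metrics(rep(skill_levels(), 5), rep(skill_levels(), 5))
  expect_equal(unname(perfect$macro), rep(1, 5))

  # novice one-vs-rest slice with TP=3, FP=1, FN=1, TN=5
  y_true <- c(rep("novice", 4), rep("expert", 6))
  y_pred <- c("novice", "novice", "novice", "expert",
              "novice", rep("expert", 5))
  m <- confusion_metrics(y_true, y_pred)
  nov <- m$per_class[m$per_class$class == "novice", ]
  expect_equal(nov$TP, 3); expect_equal(nov$FP, 1)
  expect_equal(nov$FN, 1); expect_equal(nov$TN, 5)
  expect_equal(nov$accuracy, 0.8)
  expect_equal(nov$precision, 0.75)
  expect_equal(nov$recall, 0.75)
  expect_equal(nov$f1, 0.75)
  expect_equal(nov$specificity, 5 / 6)

  # constant predictor on balanced labels
  y <- rep(skill_levels(), each = 10)
  m2 <- confusion_metrics(y, rep("novice", 30))
  expect_equal(unname(m2$macro["accuracy"]), 1 / 3)
  pc <- m2$per_class
  expect_equal(pc$recall[pc$class == "novice"], 1)
  expect_equal(pc$recall[pc$class == "expert"], 0)
  # precision undefined (no predictions) for the never-predicted classes
  expect_true(is.na(pc$precision[pc$class == "expert"]))
})

test_that("metrics derived from the 3x3 matrix match per-sample counting", {
  set.seed(12)
  y_true <- sample(skill_levels(), 200, replace = TRUE)
  y_pred <- ifelse(runif(200) < 0.6, y_true, sample(skill_levels(), 200, TRUE))
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(unname(m$macro["accuracy"]), mean(y_true == y_pred))
  for (lv in skill_levels()) {
    row <- m$per_class[m$per_class$class == lv, ]
    expect_equal(row$TP, sum(y_true == lv & y_pred == lv))
    expect_equal(row$FP, sum(y_true != lv & y_pred == lv))
    expect_equal(row$FN, sum(y_true == lv & y_pred != lv))
    expect_equal(row$TN, sum(y_true != lv & y_pred != lv))
    expect_equal(row$TP + row$FP + row$FN + row$TN, 200)
  }
  expect_true(m$macro["f1"] <= max(m$per_class$f1, na.rm = TRUE) + 1e-12)
  expect_true(m$macro["f1"] >= min(m$per_class$f1, na.rm = TRUE) - 1e-12)
})

test_that("ROC curves are monotone, oracle-exact and transform-invariant", {
  # perfectly ordered scores
  y <- rep(c("novice", "expert"), each = 10)
  scores <- cbind(novice = c(seq(0.9, 0.99, length.out = 10),
                             seq(0.01, 0.1, length.out = 10)),
                  expert = c(seq(0.1, 0.01, length.out = 10),
                             seq(0.99, 0.9, length.out = 10)))
  roc <- roc_one_vs_rest(scores, y)
  expect_equal(roc$novice$auc, 1)
  expect_equal(roc$expert$auc, 1)
  for (lv in names(roc)) {
    expect_equal(roc[[lv]]$fpr[1], 0); expect_equal(roc[[lv]]$tpr[1], 0)
    expect_equal(tail(roc[[lv]]$fpr, 1), 1)
    expect_equal(tail(roc[[lv]]$tpr, 1), 1)
    expect_true(all(diff(roc[[lv]]$fpr) >= 0))
    expect_true(all(diff(roc[[lv]]$tpr) >= 0))
  }

  # AUC equals the rank oracle, including under ties
  set.seed(14)
  y2 <- sample(c("novice", "expert"), 150, replace = TRUE)
  s2 <- round(runif(150), 2)  # rounding forces ties
  sm <- cbind(novice = s2, expert = 1 - s2)
  roc2 <- roc_one_vs_rest(sm, y2)
  expect_equal(roc2$novice$auc, brute_auc(s2, y2 == "novice"), tolerance = 1e-12)

  # label-independent scores give AUC ~ 0.5; monotone transform preserves AUC
  set.seed(15)
  y3 <- sample(c("novice", "expert"), 300, replace = TRUE)
  s3 <- rnorm(300)
  roc3 <- roc_one_vs_rest(cbind(novice = s3, expert = -s3), y3)
  expect_equal(roc3$novice$auc, 0.5, tolerance = 0.1 / 0.5)
  roc3t <- roc_one_vs_rest(cbind(novice = exp(s3), expert = -s3), y3)
  expect_equal(roc3t$novice$auc, roc3$novice$auc, tolerance = 1e-12)
})

test_that("muscle-set evaluation enumerates runs and finds planted signal", {
  tab <- make_fake_trial_table(n_subj_per_class = 6, trials = 3,
                               signal_muscles = "ECU", seed = 21)
  rep6 <- evaluate_muscle_sets(tab, as.list(muscle_names()),
                               split_spec(grouping = "subject", seed = 2),
                               seed = 2)
  expect_equal(nrow(rep6$metrics), 18)
  rf <- rep6$metrics[rep6$metrics$model == "rf", ]
  expect_equal(rf$muscle_set[which.max(rf$accuracy)], "ECU")
  # determinism of the full report
  rep6b <- evaluate_muscle_sets(tab, as.list(muscle_names()),
                                split_spec(grouping = "subject", seed = 2),
                                seed = 2)
  expect_identical(rep6$metrics, rep6b$metrics)
  expect_error(evaluate_muscle_sets(tab, list("forearm")), "unknown muscle")
})
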