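# Independent brute-force oracles and small signal builders used across
# the suite.  These deliberately re-derive quantities with naive loops so
# they share no code with the package implementations they check.

# sample entropy by direct double-loop template counting
# (templates i = 1..N-m so every counted template has an m+1 extension)
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# approximate entropy by direct phi computation, self-matches included
brute_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    nt <- n - mm + 1
    cnt <- numeric(nt)
    for (i in 1:nt) {
      for (j in 1:nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) {
          cnt[i] <- cnt[i] + 1
        }
      }
    }
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

# correlation sum by explicit O(N^2) pair loop, strict inequality
brute_corr_sum <- function(pts, r) {
  n <- nrow(pts)
  cnt <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < r) cnt <- cnt + 1
    }
  }
  2 * cnt / (n * (n - 1))
}

# AUC as the probability a random positive outscores a random negative,
# ties counted 1/2
brute_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

logistic_map <- function(n, x0 = 0.4) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

make_channel <- function(samples, fs = 2000, kind = "emg") {
  sensor_channel(samples, fs, kind)
}

# small labeled feature table: k informative features (class-shifted
# means), k_noise pure-noise features, n rows per class
make_selection_table <- function(n_per_class = 100, k_info = 5, k_noise = 5,
                                 d = 2, seed = 1) {
  set.seed(seed)
  skills <- rep(skill_levels(), each = n_per_class)
  shift <- (as.numeric(factor(skills, levels = skill_levels())) - 1) * d
  tab <- data.frame(subject = sprintf("S%03d", seq_along(skills)),
                    skill = skills)
  for (k in seq_len(k_info)) tab[[sprintf("info_%d", k)]] <- rnorm(length(skills), shift)
  for (k in seq_len(k_noise)) tab[[sprintf("noise_%d", k)]] <- rnorm(length(skills))
  tab
}

# tiny trial-level feature table in the package's layout, with group signal
# planted only in the named muscles
make_fake_trial_table <- function(n_subj_per_class = 6, trials = 3,
                                  muscles = muscle_names(),
                                  signal_muscles = muscles, seed = 1) {
  set.seed(seed)
  rows <- list()
  sid <- 0
  for (skill in skill_levels()) {
    mu <- (match(skill, skill_levels()) - 1) * 3
    for (s in seq_len(n_subj_per_class)) {
      sid <- sid + 1
      subj_eff <- rnorm(1, 0, 0.3)
      for (m in muscles) {
        planted <- if (m %in% signal_muscles) mu else 0
        for (tr in seq_len(trials)) {
          rows[[length(rows) + 1]] <- data.frame(
            subject = sprintf("S%02d", sid), skill = skill, task = "pegboard",
            trial = tr, muscle = m, side = "left",
            f1 = rnorm(1, planted + subj_eff),
            f2 = rnorm(1, planted / 2 + subj_eff))
        }
      }
    }
  }
  do.call(rbind, rows)
}
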