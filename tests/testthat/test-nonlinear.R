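test_that("resultant acceleration is the samplewise Euclidean norm", {
  mk <- function(v, kind) sensor_channel(v, 100, kind)
  r <- resultant_acceleration(mk(c(3, 0, 1), "acc_x"), mk(c(4, 0, 1), "acc_y"),
                              mk(c(0, 1e-12, 1), "acc_z"))
  expect_equal(r$samples, c(5, 1e-12, sqrt(3)))
  expect_error(resultant_acceleration(mk(1:3, "acc_x"), mk(1:2, "acc_y"),
                                      mk(1:3, "acc_z")),
               "mismatched lengths")
})

test_that("delay embedding produces the lagged coordinate matrix", {
  expect_equal(delay_embed(c(1, 2, 3, 4), 2, 1),
               rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(delay_embed(1:5, 1, 3), matrix(1:5, ncol = 1))
  expect_equal(nrow(delay_embed(rnorm(100), 3, 5)), 90)
  expect_error(delay_embed(1:5, 3, 4), "too short")
})

test_that("correlation sum equals the brute-force pair count", {
  expect_equal(correlation_sum(rbind(c(0, 0), c(0, 0)), 0.1), 1.0)
  # collinear points with exactly representable distances 1, 1, 2
  lin <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(correlation_sum(lin, 0.5), 0.0)
  expect_equal(correlation_sum(lin, 1.0), 0.0)  # strict inequality at r = d
  expect_equal(correlation_sum(lin, 1.5), 2 / 3)
  expect_equal(correlation_sum(lin, 2.5), 1.0)
  set.seed(8)
  pts <- cbind(runif(50), runif(50))
  expect_identical(as.numeric(correlation_sum(pts, 0.2)), brute_corr_sum(pts, 0.2))
  for (r in c(0.05, 0.3, 0.7)) {
    expect_identical(as.numeric(correlation_sum(pts, r)), brute_corr_sum(pts, r))
  }
  expect_error(correlation_sum(pts, -1), "positive")
})

test_that("correlation dimension recovers line and square dimensions", {
  set.seed(17)
  u <- runif(2000)
  line <- cbind(u, 2 * u)
  expect_equal(surgskill:::corr_dim_points(line), 1.0, tolerance = 0.15)
  square <- cbind(runif(2000), runif(2000))
  expect_equal(surgskill:::corr_dim_points(square), 2.0, tolerance = 0.1)
  const <- correlation_dimension(rep(1, 500))
  expect_equal(as.numeric(const), 0)
  expect_match(attr(const, "flagged"), "constant")
})

test_that("ApEn and SampEn match brute-force template counting exactly", {
  expect_equal(approximate_entropy(rep(2, 50), 2, 0.1), 0)
  # ApEn of a strictly periodic series vanishes up to its O(1/N) edge bias
  per <- rep(c(1, 2), 150)
  expect_lt(abs(approximate_entropy(per, 2, 0.1)), 1e-3)
  # summation order differs between the two code paths; agreement is at
  # machine-epsilon scale on a value of ~5e-6
  expect_lt(abs(approximate_entropy(per, 2, 0.1) - brute_apen(per, 2, 0.1)),
            1e-12)
  expect_equal(as.numeric(sample_entropy(rep(2, 50), 2, 0.1)), 0)
  expect_lt(abs(as.numeric(sample_entropy(per, 2, 0.1))), 1e-6)

  for (seed in 1:5) {
    set.seed(seed)
    x <- runif(300)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, 2, r), brute_apen(x, 2, r),
                 tolerance = 1e-12)
    expect_equal(as.numeric(sample_entropy(x, 2, r)), brute_sampen(x, 2, r),
                 tolerance = 1e-12)
  }
  expect_error(sample_entropy(runif(100), 2, 0), "positive")
  # no matches -> flagged NA, not a silent infinity
  far <- seq(0, 1000, length.out = 50)
  out <- sample_entropy(far, 2, 1e-6)
  expect_true(is.na(out))
  expect_false(is.null(attr(out, "flagged")))
})

test_that("entropies are offset-invariant and scale-invariant with relative r", {
  set.seed(4)
  x <- rnorm(250)
  r <- 0.2 * sd(x)
  expect_equal(as.numeric(sample_entropy(x, 2, r)),
               as.numeric(sample_entropy(x + 100, 2, r)), tolerance = 1e-10)
  expect_equal(as.numeric(sample_entropy(3 * x, 2, 0.2 * sd(3 * x))),
               as.numeric(sample_entropy(x, 2, r)), tolerance = 1e-10)
  expect_equal(approximate_entropy(x + 50, 2, r), approximate_entropy(x, 2, r),
               tolerance = 1e-10)
})

test_that("coarse-graining averages non-overlapping windows", {
  x <- rnorm(37)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(coarse_grain(c(1, 1, 2, 2, 3, 3), 2), c(1, 2, 3))
  expect_length(coarse_grain(1:10, 3), 3)
  expect_equal(coarse_grain(1:10, 3), c(2, 5, 8))
  expect_error(coarse_grain(x, 0), "scale")
})

test_that("multiscale entropy obeys its identities and white-noise decay", {
  set.seed(19)
  x <- rnorm(600)
  mse <- multiscale_entropy(x, scales = 1)
  expect_identical(mse$mse_per_scale[1],
                   as.numeric(sample_entropy(x, 2, 0.2 * sd(x))))
  const <- multiscale_entropy(rep(1, 400), scales = 1:5)
  expect_equal(const$mse_per_scale, rep(0, 5))
  set.seed(20)
  big <- rnorm(5000)
  curve <- multiscale_entropy(big, scales = 1:10)$mse_per_scale
  inversions <- sum(diff(curve) > 0)
  expect_lte(inversions, 1)
})

test_that("Rosenstein exponent recovers the logistic map and flatlines on a sinusoid", {
  p_map <- nonlinear_params(m_embed = 2, tau = 1, k_min = 2, k_max = 5,
                            min_sep = 10)
  est <- vapply(c(0.3, 0.4, 0.55), function(x0) {
    lyapunov_rosenstein(logistic_map(2000, x0), p_map, fs = 1)$lye
  }, numeric(1))
  expect_true(all(abs(est - log(2)) <= 0.07))

  sn <- sin(2 * pi * (0:1999) / 100)
  ros <- lyapunov_rosenstein(sn, nonlinear_params(m_embed = 3), fs = 1)
  expect_lte(abs(ros$lye), 0.05)
})

test_that("Rosenstein divergence rises early for chaos and the Lorenz rate matches", {
  tr <- surgskill:::lorenz_trajectory(6000, dt = 0.02, transient = 1000)
  p <- nonlinear_params(m_embed = 3, max_points = 6000, k_min = 50, k_max = 100)
  r <- lyapunov_rosenstein(tr[, 1], p, fs = 50)
  # published largest exponent of this flow is ~0.906 per unit time
  expect_equal(r$lye, 0.906, tolerance = 0.25)
  early <- r$divergence[seq(5, 50, 5)]
  expect_true(all(diff(early) > 0))
})

test_that("Wolf exponent separates chaotic from periodic dynamics", {
  p_map <- nonlinear_params(m_embed = 2, tau = 1, min_sep = 10)
  w <- lyapunov_wolf(logistic_map(2000), p_map, fs = 1)
  expect_equal(w, log(2), tolerance = 0.3)
  sn <- sin(2 * pi * (0:1999) / 100)
  expect_lte(abs(lyapunov_wolf(sn, nonlinear_params(m_embed = 3), fs = 1)), 0.05)
})

test_that("Wolf and Rosenstein agree in sign on mixed-complexity series", {
  agree <- 0
  for (s in 1:20) {
    w_mix <- c(0.1 + 0.8 * (s %% 5) / 5, 0, 0)
    w_mix[2] <- (1 - w_mix[1]) * 0.6
    w_mix[3] <- 1 - w_mix[1] - w_mix[2]
    acc <- generate_acc_channels(complexity_profile(w_mix[1], w_mix[2], w_mix[3]),
                                 10, 100, seed = s)
    res <- resultant_acceleration(acc[[1]], acc[[2]], acc[[3]])
    p <- nonlinear_params()
    ros <- lyapunov_rosenstein(res, p)$lye
    wol <- lyapunov_wolf(res, p)
    if (is.finite(ros) && is.finite(wol) && sign(ros) == sign(wol)) {
      agree <- agree + 1
    }
  }
  expect_gte(agree, 17)
})

test_that("generalized Hurst recovers noise, walk and ramp exponents", {
  hs <- vapply(1:50, function(s) {
    set.seed(s)
    generalized_hurst(rnorm(5000))
  }, numeric(1))
  expect_equal(mean(hs), 0.5, tolerance = 0.08 / 0.5)
  expect_equal(generalized_hurst(seq(0, 1, length.out = 5000)), 1.0,
               tolerance = 0.02)
  set.seed(60)
  walk <- cumsum(rnorm(5000))
  expect_equal(generalized_hurst(walk), 1.0, tolerance = 0.05)
  flagged <- generalized_hurst(rep(2, 500))
  expect_true(is.na(flagged))
  expect_error(generalized_hurst(rnorm(50)), "100 samples")
})

test_that("the accelerometer feature vector flags degeneracy and orders complexity", {
  mk <- function(v, kind) sensor_channel(v, 100, kind)
  const_rec <- recording("S01", "novice", "pegboard", 1, "ECU", "left",
                         emg = make_channel(rnorm(20000), 2000),
                         acc = list(mk(rep(1, 1000), "acc_x"),
                                    mk(rep(0.5, 1000), "acc_y"),
                                    mk(rep(0.2, 1000), "acc_z")),
                         baseline_emg = make_channel(rnorm(2000), 2000),
                         mvc_value = 100)
  fv <- acc_feature_vector(const_rec)
  expect_equal(fv[["ApEn"]], 0)
  expect_equal(fv[["SampEn"]], 0)
  expect_equal(fv[["CorrDim"]], 0)

  noisy <- generate_acc_channels(complexity_profile(0.1, 0.2, 0.7), 10, 100, 31)
  smooth <- generate_acc_channels(complexity_profile(0.9, 0.1, 0), 10, 100, 31)
  as_rec <- function(acc) {
    recording("S01", "novice", "pegboard", 1, "ECU", "left",
              emg = make_channel(rnorm(20000), 2000), acc = acc,
              baseline_emg = make_channel(rnorm(2000), 2000), mvc_value = 100)
  }
  f_noisy <- acc_feature_vector(as_rec(noisy))
  f_smooth <- acc_feature_vector(as_rec(smooth))
  for (f in c("ApEn", "SampEn", "MeanMSE")) {
    expect_gt(f_noisy[[f]], f_smooth[[f]])
  }
  expect_identical(acc_feature_vector(as_rec(noisy)), f_noisy)
})
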