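#' Nonlinear movement-variability features
#'
#' Entropy, fractal-dimension, Lyapunov and long-range-correlation
#' statistics of the resultant acceleration signal.  These quantify how
#' regular, predictable and structured a movement is: practiced movement is
#' smoother and more regular (low entropy, low divergence), erratic
#' movement is noisier and more complex.
#'
#' @name nonlinear-features
NULL

#' Default parameters for the nonlinear features
#'
#' @param m_entropy embedding (template) length for ApEn/SampEn/MSE.
#' @param m_embed embedding dimension for correlation dimension and
#'   Lyapunov estimation.
#' @param tau embedding lag in samples; `NULL` selects the first minimum of
#'   the average mutual information (falling back to the first zero crossing
#'   of the autocorrelation).
#' @param r_frac entropy tolerance as a fraction of the series SD.
#' @param scales coarse-graining factors for multiscale entropy.
#' @param k_min,k_max Rosenstein expansion range in samples; `NULL` for
#'   `k_max` uses `min(fs, usable range)`.
#' @param min_sep minimum temporal separation for nearest neighbours in
#'   samples; `NULL` uses the mean period (reciprocal of the
#'   power-weighted mean frequency).
#' @param n_radii number of radii for the correlation-sum fit.
#' @param radius_quantiles pairwise-distance quantiles bounding the
#'   correlation-sum scaling region.
#' @param hurst_q moment order of the structure function.
#' @param hurst_max_lag largest lag of the structure-function fit.
#' @param wolf_evolve Wolf evolution interval in samples.
#' @param wolf_scale_max neighbour search radius as a fraction of the
#'   attractor extent.
#' @param max_points embedded series longer than this are decimated before
#'   the O(N^2) kernels.
#' @return list of parameters.
#' @export
nonlinear_params <- function(m_entropy = 2, m_embed = 3, tau = NULL,
                             r_frac = 0.2, scales = 1:10,
                             k_min = 1, k_max = NULL, min_sep = NULL,
                             n_radii = 12, radius_quantiles = c(0.01, 0.1),
                             hurst_q = 2, hurst_max_lag = 19,
                             wolf_evolve = 5, wolf_scale_max = 0.2,
                             max_points = 1500) {
  if (r_frac <= 0) stop_invalid("r_frac must be positive")
  if (any(scales < 1)) stop_invalid("all coarse-grain scales must be >= 1")
  if (!is.null(k_max) && k_min >= k_max) stop_invalid("k_min must be < k_max")
  list(m_entropy = m_entropy, m_embed = m_embed, tau = tau, r_frac = r_frac,
       scales = as.integer(scales), k_min = k_min, k_max = k_max,
       min_sep = min_sep, n_radii = n_radii,
       radius_quantiles = radius_quantiles, hurst_q = hurst_q,
       hurst_max_lag = hurst_max_lag, wolf_evolve = wolf_evolve,
       wolf_scale_max = wolf_scale_max, max_points = max_points)
}

#' Resultant acceleration
#'
#' Samplewise Euclidean norm of the three accelerometer axes.
#'
#' @param acc_x,acc_y,acc_z [sensor_channel]s of equal length and rate.
#' @return [sensor_channel]-like list with non-negative `samples` and `fs`.
#' @export
resultant_acceleration <- function(acc_x, acc_y, acc_z) {
  xs <- acc_x$samples; ys <- acc_y$samples; zs <- acc_z$samples
  if (length(xs) != length(ys) || length(ys) != length(zs)) {
    stop_invalid("accelerometer axes have mismatched lengths (%d, %d, %d)",
                 length(xs), length(ys), length(zs))
  }
  if (acc_x$fs != acc_y$fs || acc_y$fs != acc_z$fs) {
    stop_invalid("accelerometer axes have mismatched sampling rates")
  }
  structure(list(samples = sqrt(xs^2 + ys^2 + zs^2), fs = acc_x$fs),
            class = "resultant_series")
}

#' Delay embedding
#'
#' Reconstructs m-dimensional state vectors from a scalar series using
#' lagged copies: point i is `(x_i, x_{i+tau}, ..., x_{i+(m-1) tau})`.
#'
#' @param series numeric vector or channel-like list.
#' @param m embedding dimension (>= 1).
#' @param tau lag in samples (>= 1).
#' @return matrix with `length(x) - (m - 1) * tau` rows and `m` columns.
#' @export
delay_embed <- function(series, m, tau) {
  x <- if (is.list(series)) series$samples else series
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1 || tau < 1) stop_invalid("m and tau must be positive integers")
  need <- (m - 1) * tau + 1
  if (length(x) < need) {
    stop_invalid("series too short for embedding: need >= %d samples, have %d",
                 need, length(x))
  }
  n <- length(x) - (m - 1) * tau
  out <- matrix(0, n, m)
  for (k in seq_len(m)) out[, k] <- x[seq_len(n) + (k - 1) * tau]
  out
}

# first minimum of average mutual information (16-bin histogram), falling
# back to the first zero crossing of the autocorrelation
select_tau <- function(x, max_lag = 50) {
  n <- length(x)
  max_lag <- min(max_lag, n %/% 4)
  if (max_lag < 2) return(1L)
  nb <- 16
  br <- seq(min(x), max(x), length.out = nb + 1)
  br[1] <- br[1] - 1e-9; br[nb + 1] <- br[nb + 1] + 1e-9
  bins <- cut(x, br, labels = FALSE)
  ami <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    a <- bins[1:(n - lag)]; b <- bins[(1 + lag):n]
    tab <- table(a, b) / (n - lag)
    pa <- rowSums(tab); pb <- colSums(tab)
    nz <- tab > 0
    ami[lag] <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  }
  for (lag in 2:max_lag) {
    if (ami[lag - 1] < ami[lag]) return(as.integer(lag - 1))
  }
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  z <- which(ac <= 0)
  if (length(z) > 0) as.integer(z[1]) else as.integer(max_lag)
}

# power-weighted mean frequency -> mean period in samples
mean_period_samples <- function(x, fs = 1) {
  n <- length(x)
  x <- x - mean(x)
  spec <- Mod(fft(x))^2
  idx <- 2:(n %/% 2)
  freqs <- (idx - 1) * fs / n
  p <- spec[idx]
  if (sum(p) <= 0) return(as.integer(max(1, n %/% 10)))
  mf <- sum(freqs * p) / sum(p)
  max(1L, as.integer(round(fs / mf)))
}

decimate_series <- function(x, max_points) {
  if (length(x) <= max_points) return(x)
  x[seq(1, length(x), length.out = max_points)]
}

#' Correlation sum
#'
#' `C(r) = 2 / (N (N - 1)) * #\{pairs i < j : ||Y_i - Y_j|| < r\}`, with the
#' Euclidean norm and strict inequality (a Heaviside step that is zero at
#' zero), so pairs at distance exactly `r` do not count.
#'
#' @param points embedded point matrix (rows = points).
#' @param radius positive radius or vector of radii.
#' @return C(r) in \[0, 1\], same length as `radius`, non-decreasing in `r`.
#' @export
correlation_sum <- function(points, radius) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  if (nrow(points) < 2) stop_invalid("correlation sum needs at least 2 points")
  if (any(radius <= 0)) stop_invalid("radius must be positive")
  cpp_corr_sum(points, as.numeric(radius))
}

# slope of log C(r) vs log r over radii with C > 0
corr_dim_points <- function(points, n_radii = 12, radius_quantiles = c(0.01, 0.1)) {
  n <- nrow(points)
  samp <- points[seq(1, n, length.out = min(n, 400)), , drop = FALSE]
  dists <- as.numeric(dist(samp))
  dists <- dists[dists > 0]
  if (length(dists) < 10) {
    return(structure(0, flagged = "degenerate"))
  }
  qs <- quantile(dists, radius_quantiles, names = FALSE)
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  cr <- correlation_sum(points, radii)
  keep <- cr > 0
  if (sum(keep) < 2) {
    return(structure(NA_real_, flagged = "all correlation sums zero in region"))
  }
  fit <- stats::lm.fit(cbind(1, log(radii[keep])), log(cr[keep]))
  unname(fit$coefficients[2])
}

#' Grassberger-Procaccia correlation dimension
#'
#' Least-squares slope of `log C(r)` versus `log r` over a geometric radius
#' grid spanning configured quantiles of the pairwise-distance
#' distribution.  A constant series is a single-point attractor and is
#' returned as 0 with a `"flagged"` attribute.
#'
#' @param series numeric vector or channel-like list.
#' @param params [nonlinear_params()].
#' @return slope estimate (the correlation dimension).
#' @export
correlation_dimension <- function(series, params = nonlinear_params()) {
  x <- if (is.list(series)) series$samples else series
  x <- decimate_series(x, params$max_points)
  if (sd(x) == 0) return(structure(0, flagged = "constant series"))
  tau <- if (is.null(params$tau)) select_tau(x) else params$tau
  pts <- delay_embed(x, params$m_embed, tau)
  corr_dim_points(pts, params$n_radii, params$radius_quantiles)
}

#' Approximate entropy
#'
#' `Phi_m - Phi_{m+1}` with self-matches included, Chebyshev template
#' distance and absolute tolerance `r_abs`.
#'
#' @param series numeric vector or channel-like list.
#' @param m template length.
#' @param r_abs absolute tolerance (use `r_frac * sd(x)` for the
#'   SD-relative convention).
#' @return non-negative scalar (up to floating error).
#' @export
approximate_entropy <- function(series, m = 2, r_abs) {
  x <- if (is.list(series)) series$samples else series
  if (r_abs <= 0) stop_invalid("r_abs must be positive")
  if (length(x) < 3 * m) stop_invalid("series too short for ApEn (need >= %d)", 3 * m)
  cpp_apen_phi(x, m, r_abs) - cpp_apen_phi(x, m + 1L, r_abs)
}

#' Sample entropy
#'
#' `-ln(A / B)` with `B` the number of template pairs matching at length
#' `m` and `A` at length `m + 1`, Chebyshev distance, self-matches
#' excluded.  When no pairs match (`B = 0` or `A = 0`) the result is `NA`
#' with a `"flagged"` attribute rather than a silent infinity.
#'
#' @inheritParams approximate_entropy
#' @return non-negative scalar, or flagged `NA`.
#' @export
sample_entropy <- function(series, m = 2, r_abs) {
  x <- if (is.list(series)) series$samples else series
  if (r_abs <= 0) stop_invalid("r_abs must be positive")
  if (length(x) < 3 * m) stop_invalid("series too short for SampEn (need >= %d)", 3 * m)
  ab <- cpp_sampen_counts(x, as.integer(m), r_abs)
  if (ab[2] == 0) return(structure(NA_real_, flagged = "no m-template matches"))
  if (ab[1] == 0) return(structure(NA_real_, flagged = "no (m+1)-template matches"))
  -log(ab[1] / ab[2])
}

#' Coarse-grain a series
#'
#' Non-overlapping window means of length `scale`; output length
#' `floor(N / scale)` (trailing remainder dropped).
#'
#' @param series numeric vector or channel-like list.
#' @param scale window length (integer >= 1).
#' @return numeric vector.
#' @export
coarse_grain <- function(series, scale) {
  x <- if (is.list(series)) series$samples else series
  scale <- as.integer(scale)
  if (scale < 1) stop_invalid("scale must be >= 1")
  if (length(x) < scale) stop_invalid("series shorter than scale")
  if (scale == 1) return(x)
  nw <- length(x) %/% scale
  colMeans(matrix(x[seq_len(nw * scale)], nrow = scale))
}

#' Multiscale entropy
#'
#' Sample entropy of the coarse-grained series at each scale.  The
#' tolerance is fixed at `r_frac * sd(original series)` across all scales
#' (the standard convention; set `r_per_scale = TRUE` for per-scale
#' tolerances).  Scales whose SampEn is undefined are flagged absent and
#' excluded from the mean/variance.
#'
#' @param series numeric vector or channel-like list.
#' @param m template length.
#' @param r_frac tolerance as fraction of SD.
#' @param scales integer coarse-graining factors.
#' @param r_per_scale recompute the tolerance from each coarse-grained
#'   series' SD instead.
#' @return list with `mse_per_scale`, `mean_mse`, `var_mse`, `n_defined`.
#' @export
multiscale_entropy <- function(series, m = 2, r_frac = 0.2, scales = 1:10,
                               r_per_scale = FALSE) {
  x <- if (is.list(series)) series$samples else series
  r0 <- r_frac * sd(x)
  vals <- vapply(scales, function(s) {
    y <- coarse_grain(x, s)
    if (length(y) < 3 * m) return(NA_real_)
    r <- if (r_per_scale) r_frac * sd(y) else r0
    if (r <= 0) return(0)  # constant series: perfectly regular
    as.numeric(sample_entropy(y, m, r))
  }, numeric(1))
  ok <- is.finite(vals)
  list(mse_per_scale = vals,
       mean_mse = if (any(ok)) mean(vals[ok]) else NA_real_,
       var_mse = if (sum(ok) > 1) var(vals[ok]) else NA_real_,
       n_defined = sum(ok))
}

#' Largest Lyapunov exponent (Rosenstein)
#'
#' Delay-embeds the series, pairs every point with its nearest neighbour
#' at temporal separation greater than the mean period, and averages the
#' log distance between the pairs as both are advanced k steps.  The
#' exponent is the slope of a degree-1 least-squares fit to this mean
#' log-divergence curve over the expansion range `[k_min, k_max]`,
#' converted to 1/s through the sampling interval.  Short- and long-term
#' exponents are the same fit over `[1, P/2]` and `[P/2, 2P]` samples
#' (P = mean period), a common movement-variability convention.
#'
#' @param series numeric vector or channel-like list.
#' @param params [nonlinear_params()].
#' @param fs sampling rate in Hz (default from the channel, else 1).
#' @return list with `lye` (1/s), `lye_short`, `lye_long`, the divergence
#'   curve, and the parameters actually used.
#' @export
lyapunov_rosenstein <- function(series, params = nonlinear_params(), fs = NULL) {
  if (is.list(series)) {
    if (is.null(fs)) fs <- series$fs
    x <- series$samples
  } else {
    x <- series
  }
  if (is.null(fs)) fs <- 1
  x <- decimate_series(x, params$max_points)
  if (sd(x) == 0) {
    return(list(lye = structure(NA_real_, flagged = "constant series"),
                lye_short = NA_real_, lye_long = NA_real_))
  }
  tau <- if (is.null(params$tau)) select_tau(x) else params$tau
  pts <- delay_embed(x, params$m_embed, tau)
  n_emb <- nrow(pts)
  min_sep <- if (is.null(params$min_sep)) mean_period_samples(x, 1) else params$min_sep
  period <- mean_period_samples(x, 1)
  k_max <- if (is.null(params$k_max)) {
    min(max(10, round(fs)), n_emb %/% 4)
  } else {
    params$k_max
  }
  k_max <- min(k_max, n_emb - min_sep - 2)
  if (k_max <= params$k_min) {
    return(list(lye = structure(NA_real_, flagged = "series too short"),
                lye_short = NA_real_, lye_long = NA_real_))
  }
  usable <- n_emb - k_max
  nn <- cpp_nearest_neighbor(pts, as.integer(min_sep), as.integer(usable))
  if (mean(is.na(nn)) > 0.5) {
    return(list(lye = structure(NA_real_, flagged = "no valid neighbours"),
                lye_short = NA_real_, lye_long = NA_real_))
  }
  ldiv <- cpp_divergence_curve(pts, nn, as.integer(k_max))
  dt <- 1 / fs
  fit_range <- function(k_lo, k_hi) {
    k_lo <- max(1, round(k_lo)); k_hi <- min(k_max, round(k_hi))
    if (k_hi - k_lo < 1) return(NA_real_)
    ks <- k_lo:k_hi
    y <- ldiv[ks + 1]
    ok <- is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    unname(stats::lm.fit(cbind(1, ks[ok] * dt), y[ok])$coefficients[2])
  }
  list(lye = fit_range(params$k_min, k_max),
       lye_short = fit_range(1, period / 2),
       lye_long = fit_range(period / 2, 2 * period),
       divergence = ldiv, tau = tau, min_sep = min_sep,
       k_max = k_max, period = period)
}

#' Largest Lyapunov exponent (Wolf trajectory tracking)
#'
#' Follows a fiducial trajectory through the reconstructed state space,
#' repeatedly measuring the growth of the distance to a nearby comparison
#' point over a fixed evolution interval, then replacing the comparison
#' point with the nearest available neighbour within the search radius.
#' The exponent is the accumulated log growth divided by the elapsed time.
#'
#' @inheritParams lyapunov_rosenstein
#' @return scalar exponent in 1/s, or flagged `NA` when too few
#'   neighbours exist.
#' @export
lyapunov_wolf <- function(series, params = nonlinear_params(), fs = NULL) {
  if (is.list(series)) {
    if (is.null(fs)) fs <- series$fs
    x <- series$samples
  } else {
    x <- series
  }
  if (is.null(fs)) fs <- 1
  x <- decimate_series(x, params$max_points)
  if (sd(x) == 0) return(structure(NA_real_, flagged = "constant series"))
  tau <- if (is.null(params$tau)) select_tau(x) else params$tau
  pts <- delay_embed(x, params$m_embed, tau)
  n <- nrow(pts)
  min_sep <- if (is.null(params$min_sep)) mean_period_samples(x, 1) else params$min_sep
  evolve <- max(1L, as.integer(params$wolf_evolve))
  extent <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  eps_max <- params$wolf_scale_max * extent
  dt <- 1 / fs
  i <- 1L
  s_log <- 0
  t_tot <- 0
  n_steps <- 0L
  idx_all <- seq_len(n)
  j <- NA_integer_
  while (i + evolve <= n) {
    if (is.na(j)) {
      cand <- idx_all[abs(idx_all - i) > min_sep & idx_all + evolve <= n]
      if (length(cand) == 0) break
      dd <- sqrt(rowSums((pts[cand, , drop = FALSE] -
                            matrix(pts[i, ], length(cand), ncol(pts), byrow = TRUE))^2))
      ok <- which(dd > 0 & dd < eps_max)
      if (length(ok) == 0) {
        i <- i + evolve
        next
      }
      j <- cand[ok[which.min(dd[ok])]]
    }
    d0 <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    i2 <- i + evolve
    j2 <- j + evolve
    if (j2 > n || d0 == 0) {
      j <- NA_integer_
      next
    }
    d1 <- sqrt(sum((pts[i2, ] - pts[j2, ])^2))
    if (d1 > 0) {
      s_log <- s_log + log(d1 / d0)
      t_tot <- t_tot + evolve * dt
      n_steps <- n_steps + 1L
    }
    i <- i2
    # replace the comparison point if it has drifted outside the scale
    j <- if (d1 >= eps_max) NA_integer_ else j2
  }
  if (n_steps < 5) return(structure(NA_real_, flagged = "insufficient neighbours"))
  s_log / t_tot
}

#' Generalized Hurst exponent
#'
#' Structure-function estimator: the input is treated as an increment
#' series, integrated (mean-removed cumulative sum), and `H(q)` is the
#' slope of `log E|y(t + lag) - y(t)|^q` versus `log lag` over lags
#' `1..max_lag`, divided by `q`.  Under this convention iid noise scores
#' 0.5 (its integral is a random walk) and a smooth trend scores 1.
#'
#' @param series numeric vector or channel-like list.
#' @param q moment order (default 2).
#' @param max_lag largest lag of the fit.
#' @return H(q) estimate; flagged `NA` for a constant series.
#' @export
generalized_hurst <- function(series, q = 2, max_lag = 19) {
  x <- if (is.list(series)) series$samples else series
  if (length(x) < 100) stop_invalid("generalized_hurst needs >= 100 samples")
  if (sd(x) == 0) return(structure(NA_real_, flagged = "constant series"))
  y <- cumsum(x - mean(x))
  lags <- seq_len(min(max_lag, length(y) %/% 4))
  sq <- vapply(lags, function(L) {
    mean(abs(y[(1 + L):length(y)] - y[1:(length(y) - L)])^q)
  }, numeric(1))
  ok <- sq > 0
  if (sum(ok) < 2) return(structure(NA_real_, flagged = "degenerate structure function"))
  slope <- unname(stats::lm.fit(cbind(1, log(lags[ok])), log(sq[ok]))$coefficients[2])
  slope / q
}

#' Nonlinear feature vector for one recording
#'
#' Computes the resultant acceleration and the nine movement-variability
#' features with their canonical column names: `ApEn`, `SampEn`,
#' `MeanMSE`, `VarMSE`, `WolfLyE`, `ShortLyE`, `LongLyE`, `CorrDim`,
#' `HurstExp` (plus `RosensteinLyE`).  Undefined sub-features propagate as
#' `NA`, never as silent zeros.
#'
#' @param rec [recording].
#' @param params [nonlinear_params()].
#' @return named numeric vector.
#' @export
acc_feature_vector <- function(rec, params = nonlinear_params()) {
  res <- resultant_acceleration(rec$acc[[1]], rec$acc[[2]], rec$acc[[3]])
  x <- res$samples
  r_abs <- params$r_frac * sd(x)
  apen <- if (r_abs > 0) approximate_entropy(x, params$m_entropy, r_abs) else 0
  sampen <- if (r_abs > 0) {
    as.numeric(sample_entropy(x, params$m_entropy, r_abs))
  } else {
    0
  }
  mse <- multiscale_entropy(x, params$m_entropy, params$r_frac, params$scales)
  ros <- lyapunov_rosenstein(res, params, fs = res$fs)
  wolf <- lyapunov_wolf(res, params, fs = res$fs)
  cd <- correlation_dimension(x, params)
  h <- generalized_hurst(x, params$hurst_q, params$hurst_max_lag)
  c(ApEn = as.numeric(apen), SampEn = sampen,
    MeanMSE = mse$mean_mse, VarMSE = mse$var_mse,
    RosensteinLyE = as.numeric(ros$lye),
    WolfLyE = as.numeric(wolf),
    ShortLyE = as.numeric(ros$lye_short), LongLyE = as.numeric(ros$lye_long),
    CorrDim = as.numeric(cd), HurstExp = as.numeric(h))
}
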