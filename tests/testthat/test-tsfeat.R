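test_that("feature vectors are deterministic and match moment theory", {
  set.seed(3)
  x <- rnorm(40000)
  fv1 <- compute_feature_vector(x, 500)
  fv2 <- compute_feature_vector(x, 500)
  expect_identical(fv1, fv2)
  expect_lt(abs(fv1$value[fv1$feature == "dist_skewness"]), 0.1)
  expect_lt(abs(fv1$value[fv1$feature == "dist_kurtosis"]), 0.1)
  expect_equal(nrow(fv1), nrow(feature_catalog()))
  expect_false(anyDuplicated(feature_catalog()$feature) > 0)

  # perfectly linear ramp: rolling 5-point linear forecast is exact
  ramp <- seq(0, 1, length.out = 2048)
  fvr <- compute_feature_vector(ramp, 500)
  expect_equal(fvr$value[fvr$feature == "fc_roll5_linear_resvar"], 0,
               tolerance = 1e-12)

  expect_error(compute_feature_vector(rnorm(100), 500), "256")
  expect_error(compute_feature_vector(c(rnorm(500), NA), 500), "finite")
})

test_that("correlation-family features are scale and offset invariant", {
  set.seed(4)
  x <- as.numeric(arima.sim(list(ar = 0.8), 4096))
  inv_fams <- c("autocorrelation", "fluctuation", "entropy")
  f_a <- compute_feature_vector(x, 500)
  f_b <- compute_feature_vector(2.7 * x + 11, 500)
  sel <- f_a$family %in% inv_fams & f_a$valid & f_b$valid
  expect_gt(sum(sel), 20)
  expect_equal(f_a$value[sel], f_b$value[sel], tolerance = 1e-8)
})

test_that("ACF first zero and fixed-lag values match theory", {
  alt <- rep(c(1, -1), 300)
  fz <- acf_first_zero(alt, fs = 100)
  expect_equal(fz$steps, 1)
  expect_true(fz$crossed)

  # densely sampled cosine: first zero crossing near a quarter period
  fs <- 1000; T_per <- 0.5
  x <- cos(2 * pi * seq(0, 10, by = 1 / fs) / T_per)
  fz2 <- acf_first_zero(x, fs)
  expect_equal(fz2$seconds, T_per / 4, tolerance = 0.01)

  ramp <- seq_len(500)
  fz3 <- acf_first_zero(ramp, fs = 100, max_lag_s = 0.1)
  expect_false(fz3$crossed)
  expect_error(acf_first_zero(rep(1, 100), 100), "Constant")

  expect_equal(acf_at_lag(rnorm(1000), 500, 0), 1)
  expect_error(acf_at_lag(rnorm(1000), 500, 10), "lag")
  set.seed(5)
  ar1 <- as.numeric(arima.sim(list(ar = 0.9), 40000))
  expect_lt(abs(acf_at_lag(ar1, 500, 0.048) - 0.9^24), 0.03)
  wn <- rnorm(40000)
  expect_lt(abs(acf_at_lag(wn, 500, 0.048)), 0.02)
})

test_that("DFA exponents match known scaling laws", {
  set.seed(6)
  alphas_w <- replicate(20, dfa(rnorm(40000))$alpha)
  expect_lt(abs(median(alphas_w) - 0.5), 0.05)
  alphas_b <- replicate(20, dfa(cumsum(rnorm(40000)))$alpha)
  expect_lt(abs(median(alphas_b) - 1.5), 0.1)

  # a straight-line signal has a quadratic cumulative profile, which
  # quadratic (order-2) detrending removes exactly: zero fluctuation at
  # every scale is flagged invalid rather than fitted
  line_res <- dfa(seq_len(4096), scales = c(16, 32, 64, 128),
                  detrend_order = 2)
  expect_false(line_res$valid)
  expect_true(is.na(line_res$alpha))

  expect_error(dfa(rnorm(1000), scales = c(2, 64)), "Smallest scale")
  expect_error(dfa(rnorm(1000), scales = c(16, 600)), "Largest scale")
})

test_that("robust sigmoid normalization matches the formula oracle", {
  m <- matrix(c(1, 2, 3, 4, 100,
                5, 5, 5, 5, 5,
                0, 1, 2, 10, 4), ncol = 3)
  fm <- fm_from_matrix(m)
  norm <- normalize_feature_matrix(fm, iqr_factor = 1)
  expect_equal(unname(norm$values[, 1]),
               sigmoid_rescale_oracle(c(1, 2, 3, 4, 100)))
  # constant feature flagged invalid
  expect_false(any(norm$valid[, 2]))
  expect_equal(unname(norm$values[, 3]),
               sigmoid_rescale_oracle(c(0, 1, 2, 10, 4)))
  # endpoints exactly 0 and 1, all values inside [0, 1]
  expect_equal(range(norm$values[, 1]), c(0, 1))
  expect_equal(norm$state, "sigmoid-scaled")

  # monotone: ordering within features preserved
  set.seed(7)
  v <- rnorm(30)
  nm <- normalize_feature_matrix(fm_from_matrix(cbind(v, rnorm(30))))
  expect_identical(order(nm$values[, 1]), order(v))

  # default 1.35 convention differs from the bare-IQR one
  n135 <- normalize_feature_matrix(fm_from_matrix(m[, c(1, 3)]))
  expect_false(isTRUE(all.equal(unname(n135$values[, 1]),
                                sigmoid_rescale_oracle(c(1, 2, 3, 4, 100)))))
  expect_equal(unname(n135$values[, 1]),
               sigmoid_rescale_oracle(c(1, 2, 3, 4, 100), iqr_divisor = 1.35))
})

test_that("group aggregation averages and prunes globally", {
  a <- fm_from_matrix(matrix(c(1, 2, 3, 4, 5, 6), ncol = 2))
  b <- fm_from_matrix(matrix(c(-1, -2, -3, 7, 8, 9), ncol = 2))
  g <- aggregate_group(list(a, b))
  expect_equal(unname(g$values[, 1]), c(0, 0, 0))
  expect_equal(unname(g$values[, 2]), c(5.5, 6.5, 7.5))

  # single participant: identity minus its own invalid features
  one <- aggregate_group(list(a))
  expect_equal(one$values, a$values)

  # a feature invalid in one participant disappears for all
  bad <- b
  bad$values[2, 2] <- NA
  bad$valid[2, 2] <- FALSE
  g2 <- aggregate_group(list(a, bad))
  expect_equal(colnames(g2$values), "f01")

  allbad <- a
  allbad$valid[] <- FALSE
  expect_error(aggregate_group(list(a, allbad)), "No feature")
})

test_that("stability curve saturates for periodic and stationary signals", {
  fs <- 200
  per <- sin(2 * pi * 2 * seq(0, 60, by = 1 / fs))
  sc <- suppressWarnings(
    stability_curve(per, fs, lengths_s = seq(5, 60, by = 5))
  )
  expect_true(all(sc$r[sc$length_s >= 15] > 0.999, na.rm = TRUE))

  set.seed(8)
  stat_sig <- as.numeric(arima.sim(list(ar = 0.7), 60 * fs))
  sc2 <- stability_curve(stat_sig, fs, lengths_s = seq(5, 60, by = 5))
  expect_gt(sc2$r[nrow(sc2)], sc2$r[1] - 0.05)
  expect_gt(sc2$r[nrow(sc2)], 0.95)

  expect_error(
    suppressWarnings(stability_curve(rnorm(600), 200, lengths_s = c(5, 10))),
    "Fewer than 2"
  )
})

test_that("long-lag ACF and DFA alpha track a graded timescale latent map", {
  geom <- gen_parcellation(15, seed = 9)
  latent <- gen_smooth_map(geom, 0.5, seed = 71)
  # knee frequency decreasing along the latent map: slower dynamics, longer
  # correlation length, larger alpha at the latent map's high end
  prof <- graded_profiles(geom, latent, knee_freq_range = c(12, 3),
                          peak_height_range = c(0, 0))
  ts <- gen_regional_timeseries(geom, 40, 509, prof$aperiodic, NULL,
                                seed = 72)
  long_acf <- apply(ts$data[[1]], 1, acf_at_lag, fs = 509, lag_s = 0.048)
  alpha <- apply(ts$data[[1]], 1, function(x) dfa(x)$alpha)
  expect_gt(cor(long_acf, latent, method = "spearman"), 0.8)
  expect_gt(cor(alpha, latent, method = "spearman"), 0.8)
})
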