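test_that("parcellation centroids are unit-norm, mirrored and labelled", {
  geom <- gen_parcellation(50, seed = 1)
  expect_equal(nrow(geom), 100)
  norms <- sqrt(geom$x^2 + geom$y^2 + geom$z^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_equal(sum(geom$hemi == "L"), sum(geom$hemi == "R"))
  left <- geom[geom$hemi == "L", ]
  right <- geom[geom$hemi == "R", ]
  expect_equal(right$x, -left$x)
  expect_equal(right$y, left$y)
  expect_equal(right$z, left$z)
  expect_true(all(left$x < 0), info = "left hemisphere strictly at x < 0")
  expect_error(gen_parcellation(1), "must be >= 2")
})

test_that("smooth maps are deterministic, standardized, and length-scaled", {
  geom <- toy_geometry()
  m1 <- gen_smooth_map(geom, 0.5, seed = 11)
  m2 <- gen_smooth_map(geom, 0.5, seed = 11)
  expect_identical(m1, m2)
  expect_equal(mean(m1), 0, tolerance = 1e-12)
  expect_equal(sd(m1), 1, tolerance = 1e-12)
  expect_error(gen_smooth_map(geom, 0), "lengthscale")

  # tiny lengthscale: near-independence between a fixed parcel pair
  draws <- gen_smooth_map(geom, 0.01, seed = 5, n_maps = 1000)
  r_small <- cor(draws[1, ], draws[2, ])
  expect_lt(abs(r_small), 0.12)
  # huge lengthscale: near-constant maps, across-parcel variance vanishing
  # relative to the unit process scale
  draws_big <- gen_smooth_map(geom, 50, seed = 5, n_maps = 200,
                              standardize = FALSE)
  across_parcel_var <- mean(apply(draws_big, 2, var))
  expect_lt(across_parcel_var, 0.02)
  expect_gt(var(colMeans(draws_big)), 0.5) # draws themselves are O(1)
})

test_that("smooth-map variogram increases with distance", {
  geom <- toy_geometry()
  cm <- as.matrix(geom[, c("x", "y", "z")])
  d <- acos(pmin(pmax(tcrossprod(cm), -1), 1))
  draws <- gen_smooth_map(geom, 0.5, seed = 9, n_maps = 250)
  iu <- upper.tri(d)
  sqdiff <- matrix(0, nrow(d), ncol(d))
  for (k in seq_len(ncol(draws))) {
    sqdiff <- sqdiff + outer(draws[, k], draws[, k], `-`)^2
  }
  sqdiff <- sqdiff / ncol(draws)
  bins <- cut(d[iu], breaks = seq(0, pi, length.out = 8))
  gamma_hat <- tapply(sqdiff[iu], bins, mean)
  gamma_hat <- gamma_hat[!is.na(gamma_hat)]
  expect_true(all(diff(gamma_hat[1:4]) > 0),
              info = "binned variogram rises over the correlated range")
})

test_that("generated time-series match their target spectrum and are seeded", {
  geom <- gen_parcellation(2, seed = 1)
  ap <- tibble::tibble(parcel = geom$parcel, offset = 0, knee = 100,
                       exponent = 2)
  ts1 <- gen_regional_timeseries(geom, 80, 509, ap, NULL, seed = 3)
  ts2 <- gen_regional_timeseries(geom, 80, 509, ap, NULL, seed = 3)
  expect_identical(ts1$data, ts2$data)
  expect_equal(ncol(ts1$data[[1]]), 40720) # 80 s at 509 Hz
  expect_equal(unname(rowMeans(ts1$data[[1]])), c(0, 0, 0, 0),
               tolerance = 1e-12)

  g1 <- geom[1, ]; class(g1) <- class(geom)
  ap1 <- ap[1, ]
  ts <- gen_regional_timeseries(g1, 80, 509, ap1, NULL, seed = 1,
                                n_participants = 20)
  pw <- sapply(seq_len(20), function(p) welch_psd(ts, participant = p)$power[1, ])
  f <- welch_psd(ts, participant = 1)$freq
  sel <- f >= 1 & f <= 60
  rel_err <- abs(rowMeans(pw)[sel] / (1 / (100 + f[sel]^2)) - 1)
  expect_lt(max(rel_err), 0.10)

  pk <- tibble::tibble(parcel = geom$parcel, center = 300, height = 0.5,
                       width = 2)
  expect_error(gen_regional_timeseries(geom, 80, 509, ap, pk),
               "Nyquist")
})

test_that("coupled feature sets have exact rank-1 structure at zero noise", {
  geom <- toy_geometry()
  cs <- gen_coupled_feature_sets(geom, 12, 8, coupling_strength = 1,
                                 noise_sd = 0, seed = 2)
  fit <- suppressWarnings(pls_fit(cs$x, cs$y))
  expect_equal(fit$effect_size[1], 1, tolerance = 1e-9)
  # exact recovery up to sign: the LV1 score map reproduces the latent map,
  # and the weight signs match the ground truth (column z-scoring reduces a
  # noiseless rank-1 matrix to sign information, so magnitudes are not
  # comparable)
  expect_equal(abs(cor(fit$x_scores[, 1], cs$truth$latent_map)), 1,
               tolerance = 1e-9)
  sgn <- sign(cor(fit$x_scores[, 1], cs$truth$latent_map))
  expect_equal(sign(sgn * fit$u[, 1]), sign(cs$truth$ts_weights),
               ignore_attr = TRUE)
  expect_error(gen_coupled_feature_sets(geom, 0, 5), ">= 1")
  expect_error(gen_coupled_feature_sets(geom, 5, 5, coupling_strength = 2),
               "0, 1")
})

test_that("donor expression reliability controls differential stability", {
  dex1 <- gen_donor_expression(3, 12, 40, reliability = 1, seed = 4)
  ds1 <- differential_stability_select(dex1)
  expect_true(all(abs(ds1$ds$ds - 1) < 1e-12))

  dex0 <- gen_donor_expression(4, 15, 2000, reliability = 0, seed = 4)
  ds0 <- differential_stability_select(dex0)
  expect_lt(abs(mean(ds0$ds$ds)), 0.02)

  dex_a <- gen_donor_expression(3, 12, 40, reliability = 0.5, seed = 8)
  dex_b <- gen_donor_expression(3, 12, 40, reliability = 0.5, seed = 8)
  expect_identical(dex_a$expr, dex_b$expr)
  expect_error(gen_donor_expression(1, 12, 40), "n_donors")
  expect_error(gen_donor_expression(3, 2, 40), "n_regions")
})
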