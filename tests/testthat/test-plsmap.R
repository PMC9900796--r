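test_that("PLS singular structure matches brute-force small-case oracles", {
  # shared single column duplicated: one latent variable carrying everything
  set.seed(15)
  v <- rnorm(12)
  x <- cbind(a = v, b = 2 * v + 1)
  y <- cbind(c = -v, d = 0.5 * v)
  rownames(x) <- rownames(y) <- paste0("P", 1:12)
  fit <- pls_fit(x, y)
  expect_equal(fit$effect_size[1], 1, tolerance = 1e-9)
  expect_equal(abs(cor(fit$x_scores[, 1], fit$y_scores[, 1])), 1,
               tolerance = 1e-9)

  # centered mutually orthogonal columns: z-scoring only rescales them, so
  # every cross-correlation — and hence every singular value — is exactly 0
  n <- 8
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 5), n))))[, -1]
  xo <- q[, 1:2]; yo <- q[, 3:4]
  colnames(xo) <- c("x1", "x2"); colnames(yo) <- c("y1", "y2")
  rownames(xo) <- rownames(yo) <- paste0("P", 1:n)
  fo <- pls_fit(xo, yo)
  expect_lt(max(abs(fo$singular_values)), 1e-9)

  # 4-parcel 2x2 toy vs hand-computed cross-correlation + closed-form SVD
  x2 <- matrix(c(1, 2, 3, 5, 2, 1, 0, 4), ncol = 2,
               dimnames = list(paste0("P", 1:4), c("x1", "x2")))
  y2 <- matrix(c(0, 1, 1, 3, 5, 4, 4, 1), ncol = 2,
               dimnames = list(paste0("P", 1:4), c("y1", "y2")))
  fit2 <- pls_fit(x2, y2)
  r_hand <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      r_hand[i, j] <- cor(x2[, i], y2[, j])
    }
  }
  # singular values of a 2x2 via its Gram eigenvalues
  g <- t(r_hand) %*% r_hand
  tr <- g[1, 1] + g[2, 2]
  dt <- g[1, 1] * g[2, 2] - g[1, 2] * g[2, 1]
  lam <- c((tr + sqrt(tr^2 - 4 * dt)) / 2, (tr - sqrt(tr^2 - 4 * dt)) / 2)
  expect_equal(fit2$singular_values, sqrt(pmax(lam, 0)), tolerance = 1e-9)

  # invariants: effect sizes sum to one, singular values nonincreasing,
  # singular vectors orthonormal
  expect_equal(sum(fit2$effect_size), 1, tolerance = 1e-9)
  expect_true(all(diff(fit2$singular_values) <= 1e-12))
  expect_equal(crossprod(fit2$u), diag(2), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(crossprod(fit2$v), diag(2), ignore_attr = TRUE,
               tolerance = 1e-9)

  expect_error(pls_fit(x2[1:2, ], y2[1:2, ]), "3 parcels")
  expect_warning(pls_fit(cbind(x2, const = 1), y2), "constant")
})

test_that("PLS is invariant to column order", {
  set.seed(16)
  x <- matrix(rnorm(20 * 5), 20, dimnames = list(NULL, paste0("x", 1:5)))
  y <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("y", 1:4)))
  rownames(x) <- rownames(y) <- paste0("P", 1:20)
  f1 <- pls_fit(x, y)
  f2 <- pls_fit(x[, c(3, 1, 5, 2, 4)], y[, c(4, 2, 1, 3)])
  expect_equal(f1$singular_values, f2$singular_values, tolerance = 1e-9)
  expect_equal(abs(cor(f1$x_scores[, 1], f2$x_scores[, 1])), 1,
               tolerance = 1e-9)
})

test_that("spin permutation test separates coupled from uncoupled data", {
  geom <- gen_parcellation(50, seed = 3)
  ens <- make_spin_ensemble(geom, 200, seed = 17)
  cs <- gen_coupled_feature_sets(geom, 15, 8, coupling_strength = 1,
                                 noise_sd = 0, seed = 18)
  pt <- pls_permutation_test(cs$x, cs$y, ens)
  expect_equal(pt$p_spin[1], 1 / 201)

  # identity permutation reproduces the observed singular value exactly
  ens_id <- make_spin_ensemble(geom, 10, seed = 19, include_identity = TRUE)
  fit <- pls_fit(cs$x, cs$y)
  xz <- scale(cs$x); yz <- scale(cs$y)
  d_id <- svd(crossprod(xz[ens_id$perms[1, ], ], yz) / (nrow(xz) - 1))$d
  expect_equal(d_id[1], fit$singular_values[1], tolerance = 1e-12)

  expect_error(pls_permutation_test(cs$x[-1, ], cs$y[-1, ], ens),
               "parcel count")
})

test_that("bootstrap loadings have ordered CIs that cover the estimate", {
  geom <- gen_parcellation(25, seed = 4)
  cs <- gen_coupled_feature_sets(geom, 8, 5, coupling_strength = 0.9,
                                 noise_sd = 0.4, seed = 20)
  boot <- pls_bootstrap_loadings(cs$x, cs$y, n_boot = 200, seed = 21)
  expect_true(all(boot$ci_lo <= boot$ci_hi + 1e-12))
  inside <- mean(boot$loading >= boot$ci_lo - 1e-9 &
                   boot$loading <= boot$ci_hi + 1e-9)
  expect_gte(inside, 0.9)

  # zero-noise rank-1 data: no sampling variability in the relation
  cs0 <- gen_coupled_feature_sets(geom, 6, 4, coupling_strength = 1,
                                  noise_sd = 0, seed = 22)
  b0 <- pls_bootstrap_loadings(cs0$x, cs0$y, n_boot = 50, seed = 23)
  expect_lt(max(abs(b0$ci_hi - b0$ci_lo)), 1e-6)
  expect_equal(abs(b0$loading), rep(1, nrow(b0)), tolerance = 1e-9)
})

test_that("distance-dependent CV splits 75/25 and respects determinism", {
  geom <- gen_parcellation(50, seed = 3)
  cs <- gen_coupled_feature_sets(geom, 10, 6, coupling_strength = 0.9,
                                 noise_sd = 0.3, seed = 24)
  cv <- distance_dependent_cv(cs$x, cs$y, geom, n_splits = 20, seed = 25)
  expect_true(all(cv$n_train == 75))
  expect_true(all(cv$n_test == 25))
  expect_false(anyDuplicated(cv$seed_parcel) > 0)
  cv2 <- distance_dependent_cv(cs$x, cs$y, geom, n_splits = 20, seed = 25)
  expect_identical(cv, cv2)

  # a deterministic shared relation survives projection: test r = 1
  v <- gen_smooth_map(geom, 0.5, seed = 26)
  xs <- cbind(a = v, b = -2 * v)
  ys <- cbind(c = 3 * v, d = v + 5)
  rownames(xs) <- rownames(ys) <- geom$parcel
  cv3 <- distance_dependent_cv(xs, ys, geom, n_splits = 10, seed = 27)
  expect_equal(abs(cv3$r_test), rep(1, 10), tolerance = 1e-9)

  expect_error(distance_dependent_cv(cs$x, cs$y, geom, n_splits = 200),
               "exceed")
})
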