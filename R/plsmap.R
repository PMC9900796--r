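# z-score columns; drop constant ones with a warning
zscore_columns <- function(m, label) {
  m <- as.matrix(m)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d constant column(s) from %s.",
                 sum(sds == 0), label))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2) abort("Fewer than 2 usable columns.")
  scale(m)
}

pls_core <- function(xz, yz) {
  r <- crossprod(xz, yz) / (nrow(xz) - 1) # entries are Pearson correlations
  s <- svd(r)
  list(u = s$u, v = s$v, d = s$d)
}

#' Partial least squares between two sets of brain maps
#'
#' Columns of `X` (parcels x time-series features) and `Y` (parcels x
#' micro-architecture maps) are z-scored; the cross-correlation matrix
#' `R = X'Y / (n - 1)` is decomposed by SVD, `R = U S V'`. Each latent
#' variable (LV) is a pair of singular vectors with its singular value
#' `s_i`; effect sizes are `eta_i = s_i^2 / sum_j s_j^2`. Brain scores are
#' the projections `XU` and `YV`; loadings are Pearson correlations between
#' original columns and their own side's scores. The `1/(n-1)` scaling makes
#' `R` a correlation matrix — any other scalar rescales `S` but leaves
#' `U`, `V`, `eta` and permutation p-values unchanged.
#'
#' @param x,y Numeric matrices or data frames with matching parcel rows
#'   (n >= 3) and non-constant columns (constant columns are dropped with a
#'   warning).
#' @param n_lv Number of latent variables to retain (default: all,
#'   `min(t, m)`).
#' @return An object of class `dyn_pls` with `u`, `v` (orthonormal columns),
#'   `singular_values`, `effect_size`, `x_scores`, `y_scores`,
#'   `x_loadings`, `y_loadings`, dimension labels, and the column
#'   means/SDs used for standardization (needed to project new parcels).
#' @export
pls_fit <- function(x, y, n_lv = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("`x` and `y` must share parcel rows.")
  if (nrow(x) < 3) abort("Need at least 3 parcels.")
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%03d", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- sprintf("y%03d", seq_len(ncol(y)))
  xz <- zscore_columns(x, "x")
  yz <- zscore_columns(y, "y")
  core <- pls_core(xz, yz)
  k <- if (is.null(n_lv)) length(core$d) else min(n_lv, length(core$d))
  u <- core$u[, seq_len(k), drop = FALSE]
  v <- core$v[, seq_len(k), drop = FALSE]
  xs <- xz %*% u
  ys <- yz %*% v
  structure(
    list(
      u = u, v = v,
      singular_values = core$d[seq_len(k)],
      effect_size = core$d^2 / sum(core$d^2),
      x_scores = xs, y_scores = ys,
      x_loadings = cor(xz, xs), y_loadings = cor(yz, ys),
      parcel = rownames(x), x_names = colnames(xz), y_names = colnames(yz),
      x_center = attr(xz, "scaled:center"), x_scale = attr(xz, "scaled:scale"),
      y_center = attr(yz, "scaled:center"), y_scale = attr(yz, "scaled:scale")
    ),
    class = "dyn_pls"
  )
}

#' @export
print.dyn_pls <- function(x, ...) {
  cat(sprintf(
    "<dyn_pls> %d parcels; %d x %d columns; LV1 effect size %.1f%%\n",
    length(x$parcel), length(x$x_names), length(x$y_names),
    100 * x$effect_size[1]
  ))
  invisible(x)
}

#' @export
glance.dyn_pls <- function(x, ...) {
  tibble(n_parcels = length(x$parcel),
         n_x = length(x$x_names), n_y = length(x$y_names),
         lv1_effect_size = x$effect_size[1],
         lv1_singular_value = x$singular_values[1],
         lv1_score_cor = cor(x$x_scores[, 1], x$y_scores[, 1],
                             method = "spearman"))
}

#' @export
tidy.dyn_pls <- function(x, lv = 1, ...) {
  bind_rows(
    tibble(side = "x", name = x$x_names, weight = x$u[, lv],
           loading = x$x_loadings[, lv]),
    tibble(side = "y", name = x$y_names, weight = x$v[, lv],
           loading = x$y_loadings[, lv])
  )
}

#' Spin permutation test for PLS latent variables
#'
#' Rows of `X` are reindexed by each spin-ensemble row (spinning one side
#' breaks the regional pairing while preserving each side's spatial
#' autocorrelation), the PLS is refit, and each observed singular value is
#' compared with the null distribution of same-rank singular values:
#' `p_i = (1 + #(null s_i >= s_i)) / (1 + n_perms)`.
#'
#' @param x,y As in [pls_fit()].
#' @param ensemble A `spin_ensemble` on the same parcellation.
#' @param n_lv Number of latent variables to report.
#' @return Tibble with `lv`, `singular_value`, `effect_size`, `p_spin`.
#' @export
pls_permutation_test <- function(x, y, ensemble, n_lv = NULL) {
  stopifnot(inherits(ensemble, "spin_ensemble"))
  x <- as.matrix(x)
  if (nrow(x) != ncol(ensemble$perms)) {
    abort("Ensemble geometry does not match the data's parcel count.")
  }
  fit <- pls_fit(x, y, n_lv = n_lv)
  k <- length(fit$singular_values)
  yz <- zscore_columns(as.matrix(y), "y")
  nulls <- matrix(NA_real_, nrow(ensemble$perms), k)
  for (r in seq_len(nrow(ensemble$perms))) {
    xp <- x[ensemble$perms[r, ], , drop = FALSE]
    d <- svd(crossprod(zscore_columns(xp, "x"), yz) / (nrow(x) - 1))$d
    nulls[r, ] <- d[seq_len(k)]
  }
  p <- vapply(seq_len(k), function(i) {
    (1 + sum(nulls[, i] >= fit$singular_values[i])) / (1 + nrow(nulls))
  }, numeric(1))
  tibble(lv = seq_len(k), singular_value = fit$singular_values,
         effect_size = fit$effect_size[seq_len(k)], p_spin = p)
}

#' Bootstrap confidence intervals for PLS loadings
#'
#' Parcel rows of `X` and `Y` are resampled jointly with replacement, the
#' PLS refit, singular-vector signs aligned to the original fit (by the sign
#' of the scalar product, preventing arbitrary flips from corrupting the
#' intervals), and loadings recomputed; percentile 2.5/97.5 bounds are
#' reported.
#'
#' @param x,y As in [pls_fit()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param lv Latent variable for which loadings are summarized.
#' @return Tibble with `side`, `name`, `loading`, `ci_lo`, `ci_hi`.
#' @export
pls_bootstrap_loadings <- function(x, y, n_boot = 1000, seed = 1L, lv = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  fit <- pls_fit(x, y)
  x <- x[, fit$x_names, drop = FALSE]
  y <- y[, fit$y_names, drop = FALSE]
  n <- nrow(x)
  boot_x <- matrix(NA_real_, n_boot, ncol(x))
  boot_y <- matrix(NA_real_, n_boot, ncol(y))
  with_seed(split_seed(seed, "pls-bootstrap"), {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) < 3) next # redraw degenerate resamples
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      sds_x <- apply(xb, 2, sd); sds_y <- apply(yb, 2, sd)
      if (any(sds_x == 0) || any(sds_y == 0)) next
      xz <- scale(xb); yz <- scale(yb)
      core <- pls_core(xz, yz)
      sgn <- sign(sum(core$u[, lv] * fit$u[, lv]))
      if (sgn == 0) sgn <- 1
      boot_x[b, ] <- cor(xz, xz %*% (sgn * core$u[, lv]))
      boot_y[b, ] <- cor(yz, yz %*% (sgn * core$v[, lv]))
      b <- b + 1L
    }
  })
  summarize_side <- function(boot, names, loadings) {
    tibble(
      name = names,
      loading = unname(loadings),
      ci_lo = apply(boot, 2, quantile, probs = 0.025),
      ci_hi = apply(boot, 2, quantile, probs = 0.975)
    )
  }
  bind_rows(
    bind_cols(tibble(side = rep("x", ncol(x))),
              summarize_side(boot_x, fit$x_names, fit$x_loadings[, lv])),
    bind_cols(tibble(side = rep("y", ncol(y))),
              summarize_side(boot_y, fit$y_names, fit$y_loadings[, lv]))
  )
}

#' Distance-dependent cross-validation of PLS brain scores
#'
#' For each split a seed parcel is drawn (without replacement across
#' splits); the training set is the 75% of parcels closest to it in
#' Euclidean centroid distance (seed included) and the test set the
#' remaining 25%. The PLS is fit on the training rows, test rows are
#' standardized with training means/SDs (no leakage) and projected onto the
#' training singular vectors, and the Spearman correlation between the two
#' test score maps (and train score maps) is recorded for LV1.
#'
#' @param x,y As in [pls_fit()].
#' @param geometry A `parcellation` aligned to the rows.
#' @param train_frac Training fraction (default 0.75).
#' @param n_splits Number of splits (default 99; cannot exceed the number of
#'   parcels).
#' @param seed Integer seed.
#' @param lv Latent variable evaluated.
#' @return Tibble with `split`, `seed_parcel`, `n_train`, `n_test`,
#'   `r_train`, `r_test`.
#' @export
distance_dependent_cv <- function(x, y, geometry, train_frac = 0.75,
                                  n_splits = 99, seed = 1L, lv = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(geometry) != n) abort("Geometry does not match data rows.")
  if (n_splits > n) abort("`n_splits` cannot exceed the number of parcels.")
  cm <- centroid_matrix(geometry)
  n_train <- round(train_frac * n)
  seeds <- with_seed(split_seed(seed, "cv-seeds"),
                     sample.int(n, n_splits, replace = FALSE))
  purrr::map_dfr(seq_len(n_splits), function(si) {
    sp <- seeds[si]
    d <- sqrt(colSums((t(cm) - cm[sp, ])^2))
    train <- order(d)[seq_len(n_train)]
    test <- setdiff(seq_len(n), train)
    xt <- x[train, , drop = FALSE]; yt <- y[train, , drop = FALSE]
    ok_x <- apply(xt, 2, sd) > 0
    ok_y <- apply(yt, 2, sd) > 0
    xz <- scale(xt[, ok_x, drop = FALSE])
    yz <- scale(yt[, ok_y, drop = FALSE])
    core <- pls_core(xz, yz)
    proj <- function(m, center, scl, w) {
      scale(m, center = center, scale = scl) %*% w
    }
    xs_te <- proj(x[test, ok_x, drop = FALSE], attr(xz, "scaled:center"),
                  attr(xz, "scaled:scale"), core$u[, lv])
    ys_te <- proj(y[test, ok_y, drop = FALSE], attr(yz, "scaled:center"),
                  attr(yz, "scaled:scale"), core$v[, lv])
    tibble(
      split = si, seed_parcel = geometry$parcel[sp],
      n_train = length(train), n_test = length(test),
      r_train = cor(xz %*% core$u[, lv], yz %*% core$v[, lv],
                    method = "spearman")[1],
      r_test = cor(xs_te, ys_te, method = "spearman")[1]
    )
  })
}
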