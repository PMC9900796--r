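#' Principal component gradient of a feature matrix
#'
#' Column-standardizes (z-scores) the valid features and performs PCA across
#' parcels: component scores are the parcel-wise gradients, component weights
#' the feature contributions, and the eigenvalue fractions the variance
#' explained. The sign of each component is fixed by orienting its scores to
#' correlate nonnegatively (Spearman) with a declared reference map — PCA
#' sign is otherwise arbitrary.
#'
#' @param x A `feature_matrix`, or a numeric matrix / data frame of parcels x
#'   features (row names = parcels).
#' @param n_components Number of components to retain (default: all).
#' @param reference_map Numeric vector used for the sign convention; default
#'   is the first feature column.
#' @return An object of class `dyn_pca`: `scores` (parcels x components),
#'   `weights` (features x components, orthonormal), `variance_fraction`,
#'   `parcel`, `feature`.
#' @export
fit_pca <- function(x, n_components = NULL, reference_map = NULL) {
  vals <- if (inherits(x, "feature_matrix")) {
    keep <- apply(x$valid, 2, all)
    x$values[, keep, drop = FALSE]
  } else {
    as.matrix(x)
  }
  if (nrow(vals) < 2 || ncol(vals) < 2) {
    abort("Need >= 2 parcels and >= 2 valid features.")
  }
  sds <- apply(vals, 2, sd)
  vals <- vals[, sds > 0, drop = FALSE]
  if (ncol(vals) < 2) abort("Fewer than 2 non-constant features.")
  z <- scale(vals)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) == 0) abort("Rank-0 matrix.")
  k <- if (is.null(n_components)) length(ev) else min(n_components, length(ev))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  weights <- pc$rotation[, seq_len(k), drop = FALSE]
  ref <- if (is.null(reference_map)) vals[, 1] else reference_map
  for (j in seq_len(k)) {
    if (cor(scores[, j], ref, method = "spearman") < 0) {
      scores[, j] <- -scores[, j]
      weights[, j] <- -weights[, j]
    }
  }
  structure(
    list(scores = scores, weights = weights,
         variance_fraction = ev / sum(ev),
         parcel = rownames(vals), feature = colnames(vals)),
    class = "dyn_pca"
  )
}

#' @export
print.dyn_pca <- function(x, ...) {
  cat(sprintf("<dyn_pca> %d parcels, %d features; PC1 explains %.1f%% of variance\n",
              length(x$parcel), length(x$feature),
              100 * x$variance_fraction[1]))
  invisible(x)
}

#' @export
tidy.dyn_pca <- function(x, ...) {
  tibble(feature = rep(x$feature, ncol(x$weights)),
         component = rep(seq_len(ncol(x$weights)), each = length(x$feature)),
         weight = as.vector(x$weights))
}

#' @export
glance.dyn_pca <- function(x, ...) {
  tibble(n_parcels = length(x$parcel), n_features = length(x$feature),
         pc1_variance_fraction = x$variance_fraction[1],
         n_components = ncol(x$scores))
}

#' @export
augment.dyn_pca <- function(x, ...) {
  out <- as_tibble(x$scores)
  names(out) <- paste0("pc", seq_len(ncol(x$scores)))
  bind_cols(tibble(parcel = x$parcel), out)
}

#' Feature loadings on a principal component, with spin significance
#'
#' Loadings are Pearson correlations between each feature column and the
#' component's score map; each is tested against spatial-autocorrelation-
#' preserving nulls and the p-values are FDR-corrected across features.
#'
#' @param x The `feature_matrix` (or matrix) the PCA was fit on.
#' @param pca A `dyn_pca` object.
#' @param ensemble A `spin_ensemble` on the same parcellation.
#' @param component Component index (default 1).
#' @param q FDR level.
#' @return Tibble with `feature`, `loading`, `p_spin`, `p_fdr`,
#'   `significant` (constant features get `NA` loadings and are excluded
#'   from the FDR family).
#' @export
component_loadings <- function(x, pca, ensemble, component = 1, q = 0.05) {
  stopifnot(inherits(pca, "dyn_pca"))
  if (component > ncol(pca$scores)) abort("Component not retained in fit.")
  vals <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  score <- pca$scores[, component]
  res <- purrr::map_dfr(seq_len(ncol(vals)), function(j) {
    col <- vals[, j]
    if (sd(col) == 0 || anyNA(col)) {
      return(tibble(feature = colnames(vals)[j], loading = NA_real_,
                    p_spin = NA_real_))
    }
    sp <- spin_pvalue(col, score, ensemble, statistic = "pearson")
    tibble(feature = colnames(vals)[j], loading = sp$estimate,
           p_spin = sp$p_spin)
  })
  ok <- !is.na(res$p_spin)
  res$p_fdr <- NA_real_
  res$significant <- NA
  if (any(ok)) {
    adj <- fdr_bh(res$p_spin[ok], q = q)
    res$p_fdr[ok] <- adj$p_fdr
    res$significant[ok] <- adj$significant
  }
  res
}

#' Spin-tested Spearman correlations between brain maps
#'
#' Correlates a reference map with each of a family of maps, assessing each
#' with the spin test and correcting across the declared family with the
#' Benjamini-Hochberg procedure.
#'
#' @param maps A data frame / matrix of maps (parcels x maps) or a named list
#'   of numeric vectors.
#' @param reference Numeric reference map (e.g. a PC1 score map).
#' @param ensemble A `spin_ensemble`.
#' @param q FDR level.
#' @return Tibble with `map`, `r_s`, `p_spin`, `p_fdr`, `significant`.
#' @export
correlate_maps <- function(maps, reference, ensemble, q = 0.05) {
  m <- if (is.list(maps) && !is.data.frame(maps)) {
    do.call(cbind, maps)
  } else {
    as.matrix(maps)
  }
  if (nrow(m) != length(reference)) abort("Mismatched parcel counts.")
  res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    sp <- spin_pvalue(reference, m[, j], ensemble, statistic = "spearman")
    tibble(map = colnames(m)[j], r_s = sp$estimate, p_spin = sp$p_spin)
  })
  adj <- fdr_bh(res$p_spin, q = q)
  res$p_fdr <- adj$p_fdr
  res$significant <- adj$significant
  res
}

#' Orthogonal Procrustes alignment of component weights
#'
#' Finds the orthogonal rotation `Q` minimizing the Frobenius distance
#' `||ref - other Q||` (closed form via SVD of `other' ref`) and returns the
#' aligned weights. Used to compare principal components across datasets
#' whose components are only defined up to rotation/sign.
#'
#' @param weights_ref,weights_other Numeric matrices (features x components)
#'   of identical dimension.
#' @return List with `aligned` (rotated `weights_other`) and `rotation`.
#' @export
procrustes_align <- function(weights_ref, weights_other) {
  weights_ref <- as.matrix(weights_ref)
  weights_other <- as.matrix(weights_other)
  if (!all(dim(weights_ref) == dim(weights_other))) {
    abort("Weight matrices must have identical dimensions.")
  }
  s <- svd(crossprod(weights_other, weights_ref))
  q <- s$u %*% t(s$v)
  list(aligned = weights_other %*% q, rotation = q)
}
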