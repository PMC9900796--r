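#' Source-level signal-to-noise ratio of a sensor model
#'
#' `SNR = 10 log10( (a^2 / N) * sum_k b_k^2 / s_k^2 )` in decibels, where
#' `a` is the source (dipole) amplitude, `b_k` the forward-model gain of
#' sensor `k` for a unit-amplitude source, and `s_k^2` the noise variance at
#' sensor `k`.
#'
#' @param gain Numeric vector of per-sensor gains `b_k`.
#' @param noise_var Numeric vector of per-sensor noise variances `s_k^2`
#'   (> 0).
#' @param amplitude Source amplitude `a`; default 10 (nAm), the typical
#'   strength of a cortical dipole.
#' @return SNR in dB (scalar).
#' @examples
#' snr_db(gain = 1, noise_var = 1, amplitude = 1) # 0 dB
#' @export
snr_db <- function(gain, noise_var, amplitude = 10) {
  if (length(gain) != length(noise_var) || length(gain) < 1) {
    abort("`gain` and `noise_var` must be equal-length, non-empty vectors.")
  }
  if (any(noise_var <= 0)) abort("All noise variances must be > 0.")
  n <- length(gain)
  10 * log10(amplitude^2 / n * sum(gain^2 / noise_var))
}

#' Remove features spatially correlated with an SNR map
#'
#' Each feature column is correlated (Pearson) with the SNR map and tested
#' with the spin test; features with `p_spin < alpha` are removed. The
#' removal is deliberately uncorrected for multiple comparisons — that is
#' the conservative direction for feature *removal*, since correction would
#' remove fewer features. Set `correct = TRUE` for an FDR-based alternative.
#'
#' @param fm A `feature_matrix`.
#' @param snr_map Numeric per-parcel SNR values (non-constant).
#' @param ensemble A `spin_ensemble`.
#' @param alpha Removal threshold on `p_spin` (default 0.05).
#' @param correct If `TRUE`, remove on FDR-adjusted p-values instead.
#' @return List with `retained` (a `feature_matrix`) and `report` (tibble
#'   `feature`, `r`, `p_spin`, `removed`).
#' @export
snr_feature_filter <- function(fm, snr_map, ensemble, alpha = 0.05,
                               correct = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (sd(snr_map) == 0) abort("Constant SNR map: correlation undefined.")
  report <- purrr::map_dfr(seq_len(ncol(fm$values)), function(j) {
    col <- fm$values[, j]
    if (anyNA(col) || sd(col) == 0) {
      return(tibble(feature = colnames(fm$values)[j], r = NA_real_,
                    p_spin = NA_real_))
    }
    sp <- spin_pvalue(col, snr_map, ensemble, statistic = "pearson")
    tibble(feature = colnames(fm$values)[j], r = sp$estimate,
           p_spin = sp$p_spin)
  })
  pvals <- if (correct) fdr_bh(report$p_spin[!is.na(report$p_spin)])$p_fdr else report$p_spin
  if (correct) {
    report$p_use <- NA_real_
    report$p_use[!is.na(report$p_spin)] <- pvals
  } else {
    report$p_use <- pvals
  }
  report$removed <- !is.na(report$p_use) & report$p_use < alpha
  report$p_use <- NULL
  keep <- report$feature[!report$removed]
  if (length(keep) == 0) abort("All features removed by the SNR filter.")
  retained <- feature_matrix(
    fm$values[, keep, drop = FALSE],
    fm$catalog %>% filter(.data$feature %in% keep),
    fm$valid[, keep, drop = FALSE],
    state = fm$state, participant = fm$participant
  )
  list(retained = retained, report = report)
}

#' Regress a covariate map out of every feature
#'
#' Ordinary least squares of each feature on an intercept plus the covariate
#' across parcels; the residual feature matrix is returned. Residuals are
#' exactly orthogonal to the centered covariate.
#'
#' @param fm A `feature_matrix`.
#' @param covariate_map Numeric per-parcel covariate (non-constant).
#' @return A `feature_matrix` of residuals (state preserved as `"raw"`).
#' @export
regress_covariate <- function(fm, covariate_map) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 3) abort("Need at least 3 parcels.")
  if (sd(covariate_map) == 0) abort("Covariate is constant.")
  h <- cbind(1, covariate_map)
  qrh <- qr(h)
  vals <- fm$values
  ok_cols <- apply(fm$valid, 2, all)
  vals[, ok_cols] <- qr.resid(qrh, vals[, ok_cols, drop = FALSE])
  vals[, !ok_cols] <- NA_real_
  valid <- fm$valid
  valid[, !ok_cols] <- FALSE
  feature_matrix(vals, fm$catalog, valid, state = "raw",
                 participant = fm$participant)
}

#' Compare the dominant component of rest and noise feature matrices
#'
#' Fits a PCA to both matrices (on the intersection of their feature
#' catalogs), Procrustes-aligns the noise weights to the rest weights, and
#' correlates the resulting first-component score maps with spin
#' significance. A high correlation would indicate that the dominant axis of
#' "dynamics" is reproduced by environmental/instrumental noise alone.
#'
#' @param rest_fm,noise_fm `feature_matrix` objects on the same parcels.
#' @param ensemble A `spin_ensemble`.
#' @param n_components Components carried into the alignment (default 5).
#' @return One-row tibble with `r`, `p_spin`, `n_features`.
#' @export
noise_component_comparison <- function(rest_fm, noise_fm, ensemble,
                                       n_components = 5) {
  stopifnot(inherits(rest_fm, "feature_matrix"),
            inherits(noise_fm, "feature_matrix"))
  shared <- intersect(colnames(rest_fm$values)[apply(rest_fm$valid, 2, all)],
                      colnames(noise_fm$values)[apply(noise_fm$valid, 2, all)])
  if (length(shared) < 10) abort("Fewer than 10 shared valid features.")
  rest <- rest_fm$values[, shared, drop = FALSE]
  noise <- noise_fm$values[, shared, drop = FALSE]
  keep <- apply(rest, 2, sd) > 0 & apply(noise, 2, sd) > 0
  rest <- rest[, keep, drop = FALSE]
  noise <- noise[, keep, drop = FALSE]
  k <- min(n_components, ncol(rest) - 1, nrow(rest) - 1)
  pca_rest <- fit_pca(rest, n_components = k)
  pca_noise <- fit_pca(noise, n_components = k)
  aligned <- procrustes_align(pca_rest$weights, pca_noise$weights)
  noise_scores <- scale(noise) %*% aligned$aligned[, 1]
  sp <- spin_pvalue(pca_rest$scores[, 1], as.vector(noise_scores), ensemble,
                    statistic = "spearman")
  tibble(r = sp$estimate, p_spin = sp$p_spin, n_features = ncol(rest))
}
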