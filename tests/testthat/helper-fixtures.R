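# Shared fixtures, built in code. Small geometries and signals reused across
# test files; everything seeded so the suite is deterministic.

toy_geometry <- function(n_per_hemisphere = 20) {
  gen_parcellation(n_per_hemisphere, seed = 42L)
}

# a psd_estimate built directly from a tabulated curve
psd_from_curve <- function(freq, power, fs = 509) {
  structure(
    list(freq = freq, power = matrix(power, 1, dimnames = list("r1", NULL)),
         fs = fs, window_s = 1 / diff(freq[1:2]), overlap = 0.5),
    class = "psd_estimate"
  )
}

# feature matrix from a plain matrix with default catalog labels
fm_from_matrix <- function(m, state = "raw") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  feature_matrix(m, state = state)
}

small_ensemble <- function(geometry, n_perms = 200, seed = 7L) {
  make_spin_ensemble(geometry, n_perms = n_perms, seed = seed)
}

# the robust sigmoid + unit rescale evaluated literally, as an oracle
sigmoid_rescale_oracle <- function(x, iqr_divisor = 1) {
  iqr <- unname(quantile(x, 0.75) - quantile(x, 0.25)) / iqr_divisor
  xn <- 1 / (1 + exp(-(x - median(x)) / iqr))
  (xn - min(xn)) / (max(xn) - min(xn))
}
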