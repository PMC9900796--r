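# Curated time-series feature catalog
#
# ~100 named, deterministic features across seven families (distribution,
# autocorrelation, forecasting, fluctuation, wavelet, entropy, spectral),
# chosen to span the families that massive feature-extraction toolboxes
# cover while staying O(n log n) per signal. Each definition is a pure
# function of shared "ingredients" (ACF, Welch PSD, cumulative profile)
# computed once per signal.

the_catalog_env <- new.env(parent = emptyenv())

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

hist_entropy <- function(x, bins) {
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  shannon(h / sum(h)) / log(bins)
}

ordinal_entropy <- function(x, m) {
  n <- length(x)
  idx <- seq_len(n - m + 1)
  code <- integer(length(idx))
  b <- 1L
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      code <- code + b * (x[idx + i - 1] < x[idx + j - 1])
      b <- b * 2L
    }
  }
  shannon(tabulate(code + 1L, nbins = b) / length(code)) / log(factorial(m))
}

word_richness <- function(x, k = 8) {
  bits <- as.integer(x > median(x))
  n <- length(bits) - k + 1
  code <- numeric(n)
  for (i in seq_len(k)) code <- code * 2 + bits[seq_len(n) + i - 1]
  length(unique(code)) / min(2^k, n)
}

haar_energies <- function(x, levels = 6) {
  e <- numeric(levels)
  s <- x
  for (j in seq_len(levels)) {
    m <- length(s) %/% 2
    if (m < 2) break
    a <- s[seq_len(m) * 2 - 1]
    b <- s[seq_len(m) * 2]
    e[j] <- sum(((a - b) / sqrt(2))^2)
    s <- (a + b) / sqrt(2)
  }
  e
}

rolling_linear_resvar <- function(x, w) {
  # one-step linear extrapolation from the previous w points; the predictor
  # is a fixed linear filter (OLS line through positions 1..w evaluated at
  # w + 1), so a perfectly linear signal has zero residuals
  i <- seq_len(w)
  wt <- 1 / w + (w + 1 - mean(i)) * (i - mean(i)) / sum((i - mean(i))^2)
  pred <- stats::filter(x, rev(wt), method = "convolution", sides = 1)
  e <- x[(w + 1):length(x)] - pred[w:(length(x) - 1)]
  var(e) / var(x)
}

rolling_mean_resvar <- function(x, w) {
  pred <- stats::filter(x, rep(1 / w, w), method = "convolution", sides = 1)
  e <- x[(w + 1):length(x)] - pred[w:(length(x) - 1)]
  var(e) / var(x)
}

spectral_rolloff <- function(f, p, frac) {
  cs <- cumsum(p) / sum(p)
  f[which(cs >= frac)[1]]
}

# shared per-signal ingredients
feature_ingredients <- function(x, fs) {
  n <- length(x)
  max_lag <- min(n - 2L, max(256L, round_half_up(2 * fs)))
  ac <- acf_fft(x, max_lag)
  wlen_s <- min(4, floor(n / 2) / fs)
  psd <- welch_psd(x, window_s = wlen_s, fs = fs)
  fpos <- psd$freq > 0
  lev <- if (is.finite(ac[2])) levinson(ac, 10, 1) else NULL
  scl <- dfa_default_scales(n)
  list(x = x, fs = fs, n = n, mu = mean(x), sdx = sd(x), ac = ac, lev = lev,
       dfa1 = dfa_both(x, scl, 1), dfa2 = dfa_both(x, scl, 2),
       freq = psd$freq[fpos], pow = psd$power[1, fpos])
}

build_catalog <- function() {
  defs <- list()
  add <- function(name, family, fn) {
    defs[[length(defs) + 1]] <<- list(name = name, family = family, fn = fn)
  }

  ## distribution -------------------------------------------------------
  add("dist_mean", "distribution", function(g) g$mu)
  add("dist_sd", "distribution", function(g) g$sdx)
  add("dist_skewness", "distribution", function(g) e1071::skewness(g$x))
  add("dist_kurtosis", "distribution", function(g) e1071::kurtosis(g$x))
  add("dist_median", "distribution", function(g) median(g$x))
  add("dist_mad", "distribution", function(g) mad(g$x))
  add("dist_iqr", "distribution", function(g) stats::IQR(g$x))
  for (q in c(0.01, 0.05, 0.25, 0.75, 0.95, 0.99)) {
    local({
      qq <- q
      add(sprintf("dist_q%02d", round(100 * qq)), "distribution",
          function(g) unname(quantile(g$x, qq)))
    })
  }
  add("dist_trimmed_mean10", "distribution", function(g) mean(g$x, trim = 0.1))
  add("dist_outlier_frac_2sd", "distribution",
      function(g) mean(abs(g$x - g$mu) > 2 * g$sdx))
  add("dist_outlier_frac_3sd", "distribution",
      function(g) mean(abs(g$x - g$mu) > 3 * g$sdx))
  add("dist_prop_above_mean", "distribution", function(g) mean(g$x > g$mu))
  add("dist_pearson_skew", "distribution",
      function(g) 3 * (g$mu - median(g$x)) / g$sdx)
  add("dist_max_abs_z", "distribution",
      function(g) max(abs(g$x - g$mu)) / g$sdx)
  add("dist_range", "distribution", function(g) diff(range(g$x)))
  add("dist_bimodality", "distribution", function(g) {
    (e1071::skewness(g$x)^2 + 1) / (e1071::kurtosis(g$x) + 3)
  })

  ## autocorrelation ----------------------------------------------------
  for (k in c(1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 24, 32, 48, 64)) {
    local({
      kk <- k
      add(sprintf("acf_lag%02d", kk), "autocorrelation",
          function(g) g$ac[kk + 1])
    })
  }
  for (ms in c(10, 20, 48, 100)) {
    local({
      mms <- ms
      add(sprintf("acf_ms%03d", mms), "autocorrelation", function(g) {
        lag <- round_half_up(mms / 1000 * g$fs)
        if (lag < 1 || lag + 1 > length(g$ac)) return(NA_real_)
        g$ac[lag + 1]
      })
    })
  }
  add("acf_first_zero", "autocorrelation", function(g) {
    idx <- which(g$ac[-1] <= 0)
    if (length(idx) == 0) NA_real_ else idx[1]
  })
  add("acf_first_below_1e", "autocorrelation", function(g) {
    idx <- which(g$ac[-1] <= exp(-1))
    if (length(idx) == 0) NA_real_ else idx[1]
  })
  add("acf_sum_10", "autocorrelation", function(g) sum(g$ac[2:11]))
  add("acf_sum_abs_50", "autocorrelation",
      function(g) sum(abs(g$ac[2:min(51, length(g$ac))])))
  add("acf_first_min", "autocorrelation", function(g) {
    d <- diff(g$ac)
    idx <- which(d[-1] > 0 & d[-length(d)] <= 0)
    if (length(idx) == 0) NA_real_ else idx[1] + 1
  })
  for (k in 1:5) {
    local({
      kk <- k
      add(sprintf("pacf_lag%d", kk), "autocorrelation",
          function(g) g$lev$pacf[kk])
    })
  }
  for (k in c(1, 24)) {
    local({
      kk <- k
      add(sprintf("acf_sq_lag%02d", kk), "autocorrelation",
          function(g) acf_fft((g$x - g$mu)^2, kk)[kk + 1])
      add(sprintf("acf_abs_lag%02d", kk), "autocorrelation",
          function(g) acf_fft(abs(g$x - g$mu), kk)[kk + 1])
    })
  }

  ## forecasting --------------------------------------------------------
  add("fc_roll5_linear_resvar", "forecasting",
      function(g) rolling_linear_resvar(g$x, 5))
  add("fc_roll10_linear_resvar", "forecasting",
      function(g) rolling_linear_resvar(g$x, 10))
  for (w in c(3, 5, 10)) {
    local({
      ww <- w
      add(sprintf("fc_mean%d_resvar", ww), "forecasting",
          function(g) rolling_mean_resvar(g$x, ww))
    })
  }
  add("fc_ar1_coef", "forecasting", function(g) g$lev$phi[1, 1])
  for (p in c(1, 2, 5)) {
    local({
      pp <- p
      # Yule-Walker prediction-error variance as a fraction of signal variance
      add(sprintf("fc_ar%d_resvar", pp), "forecasting",
          function(g) g$lev$pev[pp])
    })
  }
  add("fc_ar_best_order", "forecasting", function(g) {
    aic <- g$n * log(c(1, g$lev$pev)) + 2 * (0:10)
    as.numeric(which.min(aic) - 1)
  })

  ## fluctuation --------------------------------------------------------
  add("dfa_alpha", "fluctuation", function(g) g$dfa1$rms[1])
  add("dfa_alpha_o2", "fluctuation", function(g) g$dfa2$rms[1])
  add("dfa_alpha_meanabs", "fluctuation", function(g) g$dfa1$mean_abs[1])
  add("dfa_alpha_meanabs_o2", "fluctuation", function(g) g$dfa2$mean_abs[1])
  add("dfa_r2", "fluctuation", function(g) g$dfa1$rms[2])
  add("dfa_alpha_short", "fluctuation", function(g) {
    dfa(g$x, scales = round(2^seq(4, 7, length.out = 8)))$alpha
  })
  add("dfa_alpha_long", "fluctuation", function(g) {
    if (g$n < 4 * 2048) return(NA_real_)
    dfa(g$x, scales = round(2^seq(8, 11, length.out = 8)))$alpha
  })

  ## wavelet ------------------------------------------------------------
  for (j in 1:6) {
    local({
      jj <- j
      add(sprintf("wav_energy_l%d", jj), "wavelet", function(g) {
        e <- haar_energies(g$x)
        e[jj] / sum(e)
      })
    })
  }
  add("wav_entropy", "wavelet", function(g) {
    e <- haar_energies(g$x)
    shannon(e / sum(e)) / log(length(e))
  })
  add("wav_slope", "wavelet", function(g) {
    e <- haar_energies(g$x)
    e <- e / sum(e)
    unname(coef(lm.fit(cbind(1, seq_along(e)), log2(e + 1e-12)))[2])
  })
  add("wav_fine_coarse_ratio", "wavelet", function(g) {
    e <- haar_energies(g$x)
    sum(e[1:2]) / sum(e[5:6])
  })

  ## entropy ------------------------------------------------------------
  add("ent_hist_10", "entropy", function(g) hist_entropy(g$x, 10))
  add("ent_hist_20", "entropy", function(g) hist_entropy(g$x, 20))
  add("ent_ordinal_m3", "entropy", function(g) ordinal_entropy(g$x, 3))
  add("ent_ordinal_m4", "entropy", function(g) ordinal_entropy(g$x, 4))
  add("ent_word_richness", "entropy", function(g) word_richness(g$x))
  add("ent_diff_hist_10", "entropy", function(g) hist_entropy(diff(g$x), 10))

  ## spectral -----------------------------------------------------------
  bands <- canonical_bands()
  for (i in seq_len(nrow(bands))) {
    local({
      bn <- bands$band[i]; lo <- bands$lo[i]; hi <- bands$hi[i]
      add(sprintf("sp_logpow_%s", bn), "spectral", function(g) {
        sel <- g$freq >= lo & g$freq <= hi
        if (!any(sel)) return(NA_real_)
        log10(mean(g$pow[sel]))
      })
      add(sprintf("sp_relpow_%s", bn), "spectral", function(g) {
        sel <- g$freq >= lo & g$freq <= hi
        if (!any(sel)) return(NA_real_)
        sum(g$pow[sel]) / sum(g$pow)
      })
    })
  }
  add("sp_centroid", "spectral",
      function(g) sum(g$freq * g$pow) / sum(g$pow))
  add("sp_spread", "spectral", function(g) {
    c0 <- sum(g$freq * g$pow) / sum(g$pow)
    sqrt(sum((g$freq - c0)^2 * g$pow) / sum(g$pow))
  })
  add("sp_rolloff85", "spectral",
      function(g) spectral_rolloff(g$freq, g$pow, 0.85))
  add("sp_rolloff95", "spectral",
      function(g) spectral_rolloff(g$freq, g$pow, 0.95))
  add("sp_peak_freq", "spectral", function(g) g$freq[which.max(g$pow)])
  add("sp_entropy", "spectral", function(g) {
    p <- g$pow / sum(g$pow)
    shannon(p) / log(length(p))
  })
  add("sp_loglog_slope", "spectral", function(g) {
    sel <- g$freq >= 2 & g$freq <= 40
    if (sum(sel) < 5) return(NA_real_)
    unname(coef(lm.fit(cbind(1, log10(g$freq[sel])),
                       log10(g$pow[sel])))[2])
  })
  add("sp_log_totpow", "spectral", function(g) {
    log10(sum(g$pow) * diff(g$freq[1:2]))
  })

  defs
}

catalog_defs <- function() {
  if (is.null(the_catalog_env$defs)) the_catalog_env$defs <- build_catalog()
  the_catalog_env$defs
}

#' The curated time-series feature catalog
#'
#' @return Tibble with columns `feature` and `family` (one of distribution,
#'   autocorrelation, forecasting, fluctuation, wavelet, entropy, spectral),
#'   in extraction order. Feature names are unique and every feature is a
#'   deterministic function of a signal and its sampling rate.
#' @export
feature_catalog <- function() {
  defs <- catalog_defs()
  tibble(feature = purrr::map_chr(defs, "name"),
         family = purrr::map_chr(defs, "family"))
}

#' A small, fast feature subset for stability analysis
#'
#' Roughly twenty inexpensive features spanning all families, in the spirit
#' of minimal canonical feature sets, used by [stability_curve()].
#'
#' @return Tibble like [feature_catalog()].
#' @export
reduced_catalog <- function() {
  keep <- c("dist_sd", "dist_skewness", "dist_kurtosis", "dist_iqr",
            "dist_outlier_frac_2sd", "acf_lag01", "acf_lag05", "acf_lag24",
            "acf_first_zero", "acf_sum_10", "pacf_lag1", "fc_roll5_linear_resvar",
            "fc_mean5_resvar", "fc_ar1_coef", "dfa_alpha_short",
            "wav_entropy", "wav_slope", "ent_hist_10", "ent_ordinal_m3",
            "sp_centroid", "sp_entropy", "sp_peak_freq")
  feature_catalog() %>% filter(.data$feature %in% keep)
}

#' Compute the feature vector of one signal
#'
#' Evaluates every catalog entry on the signal. Operations that error or
#' return non-finite values are flagged invalid rather than raising, so a
#' single degenerate feature never aborts an extraction run.
#'
#' @param signal Numeric vector of at least 256 finite samples.
#' @param fs Sampling rate in Hz.
#' @param catalog Subset of [feature_catalog()] to evaluate.
#' @return Tibble with columns `feature`, `family`, `value`, `valid`.
#' @export
compute_feature_vector <- function(signal, fs, catalog = feature_catalog()) {
  if (length(signal) < 256) abort("Signal must have >= 256 samples.")
  if (!all(is.finite(signal))) abort("Signal must be finite.")
  defs <- catalog_defs()
  names(defs) <- purrr::map_chr(defs, "name")
  defs <- defs[catalog$feature]
  g <- feature_ingredients(signal, fs)
  vals <- purrr::map_dbl(defs, function(d) {
    v <- tryCatch(suppressWarnings(d$fn(g)), error = function(e) NA_real_)
    if (length(v) != 1 || !is.numeric(v)) NA_real_ else as.numeric(v)
  })
  tibble(feature = catalog$feature, family = catalog$family,
         value = unname(vals), valid = is.finite(unname(vals)))
}

#' Extract a feature matrix per participant from regional time-series
#'
#' Applies the catalog to every parcel of every participant after trimming
#' the recording: the first `drop_initial_s` seconds are discarded and the
#' next `use_s` seconds retained (when the recording is long enough).
#'
#' @param ts A `regional_ts` object.
#' @param catalog Feature catalog subset.
#' @param drop_initial_s Seconds dropped from the start (default 30).
#' @param use_s Seconds retained for extraction (default 80).
#' @return A list of `feature_matrix` objects, one per participant.
#' @export
compute_feature_matrices <- function(ts, catalog = feature_catalog(),
                                     drop_initial_s = 30, use_s = 80) {
  stopifnot(inherits(ts, "regional_ts"))
  n <- ncol(ts$data[[1]])
  want_use <- round(use_s * ts$fs)
  want_drop <- round(drop_initial_s * ts$fs)
  idx <- if (n >= want_drop + want_use) {
    want_drop + seq_len(want_use)
  } else if (n >= want_use) {
    (n - want_use) + seq_len(want_use)
  } else {
    seq_len(n)
  }
  purrr::imap(ts$data, function(mat, p) {
    vals <- t(vapply(seq_len(nrow(mat)), function(i) {
      fv <- compute_feature_vector(mat[i, idx], ts$fs, catalog)
      ifelse(fv$valid, fv$value, NA_real_)
    }, numeric(nrow(catalog))))
    dimnames(vals) <- list(ts$parcel, catalog$feature)
    feature_matrix(vals, catalog, participant = paste0("p", p))
  })
}
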