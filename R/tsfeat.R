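#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# biased (1/N) sample autocorrelation up to max_lag; FFT for long lag
# ranges, direct sums for short ones
acf_fft <- function(x, max_lag) {
  n <- length(x)
  max_lag <- min(max_lag, n - 1)
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom == 0) return(rep(NA_real_, max_lag + 1))
  if (max_lag <= 64) {
    ac <- vapply(seq_len(max_lag), function(k) {
      sum(x[seq_len(n - k)] * x[(k + 1):n])
    }, numeric(1))
    return(c(1, ac / denom))
  }
  m <- stats::nextn(2 * n, 2)
  ft <- fft(c(x, numeric(m - n)))
  ac <- Re(fft(Mod(ft)^2, inverse = TRUE))[seq_len(max_lag + 1)] / m
  ac / ac[1]
}

# Levinson-Durbin recursion on a biased ACF: AR coefficients, partial
# autocorrelations and prediction-error variances for all orders <= p_max
levinson <- function(ac, p_max, v0) {
  phi <- matrix(0, p_max, p_max)
  pacf <- numeric(p_max)
  pev <- numeric(p_max + 1)
  pev[1] <- v0
  for (p in seq_len(p_max)) {
    k <- if (p == 1) ac[2] else {
      (ac[p + 1] - sum(phi[p - 1, seq_len(p - 1)] * ac[p:2])) / pev[p]
    }
    phi[p, p] <- k
    if (p > 1) {
      phi[p, seq_len(p - 1)] <- phi[p - 1, seq_len(p - 1)] -
        k * phi[p - 1, (p - 1):1]
    }
    pacf[p] <- k
    pev[p + 1] <- pev[p] * (1 - k^2)
  }
  list(phi = phi, pacf = pacf, pev = pev[-1])
}

#' First zero-crossing of the autocorrelation function
#'
#' The smallest positive lag at which the (biased) sample autocorrelation
#' drops to or below zero; a standard summary of correlation length
#' (`t_c` in the feature catalog).
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param max_lag_s Largest lag searched, in seconds.
#' @return One-row tibble with `steps`, `seconds`, and `crossed` (`FALSE`
#'   with `NA` lags when the ACF stays positive up to `max_lag_s`).
#' @export
acf_first_zero <- function(signal, fs, max_lag_s = 2) {
  if (sd(signal) == 0) abort("Constant signal: ACF undefined.")
  max_lag <- max(1L, round_half_up(max_lag_s * fs))
  ac <- acf_fft(signal, max_lag)
  idx <- which(ac[-1] <= 0)
  if (length(idx) == 0) {
    tibble(steps = NA_integer_, seconds = NA_real_, crossed = FALSE)
  } else {
    tibble(steps = idx[1], seconds = idx[1] / fs, crossed = TRUE)
  }
}

#' Autocorrelation at a fixed time lag
#'
#' Biased sample autocorrelation at `round(lag_s * fs)` samples (half-up
#' rounding, so a 48 ms lag at ~500 Hz is 24 time steps).
#'
#' @inheritParams acf_first_zero
#' @param lag_s Lag in seconds; must round to at least 1 sample and fewer
#'   than half the signal length.
#' @return A single correlation value (`NA` for a constant signal).
#' @export
acf_at_lag <- function(signal, fs, lag_s) {
  lag <- round_half_up(lag_s * fs)
  if (lag < 0 || lag >= length(signal) / 2) {
    abort("`lag_s` must round to a lag in [0, length/2).")
  }
  if (sd(signal) == 0) return(NA_real_)
  if (lag == 0) return(1) # self-correlation
  acf_fft(signal, lag)[lag + 1]
}

# default log-spaced DFA scales for a signal of length n
dfa_default_scales <- function(n, detrend_order = 1) {
  lo <- max(16, 4 * (detrend_order + 1))
  hi <- max(lo * 10, min(floor(n / 4), 2048))
  unique(round(2^seq(log2(lo), log2(hi), length.out = 18)))
}

#' Detrended fluctuation analysis
#'
#' Cumulative-sum profile of the demeaned signal; in non-overlapping windows
#' of each scale the profile is detrended with a polynomial of order
#' `detrend_order` and the fluctuation size is summarized either as the root
#' mean square (`"rms"`) or the mean absolute residual (`"mean_abs"`). The
#' scaling exponent `alpha` is the least-squares slope of log fluctuation
#' against log scale (0.5 for uncorrelated noise, 1.5 for its cumulative sum).
#'
#' @param signal Numeric vector.
#' @param scales Window sizes in samples; default is ~18 log-spaced scales
#'   from 16 to `min(n/4, 2048)`. Must satisfy
#'   `min >= 2 * (detrend_order + 1)` and `max <= n / 4`.
#' @param detrend_order Polynomial detrending order (1 = linear).
#' @param formulation `"rms"` or `"mean_abs"` fluctuation size.
#' @return A list of class `dfa_result`: `alpha`, `r_squared`, `scales`,
#'   `fluctuation`, `valid` (`FALSE` with `alpha = NA` when any scale has
#'   exactly zero fluctuation, e.g. a perfectly detrendable signal).
#' @export
dfa <- function(signal, scales = NULL, detrend_order = 1,
                formulation = c("rms", "mean_abs")) {
  formulation <- match.arg(formulation)
  n <- length(signal)
  if (is.null(scales)) scales <- dfa_default_scales(n, detrend_order)
  scales <- sort(unique(as.integer(scales)))
  if (min(scales) < 2 * (detrend_order + 1)) {
    abort("Smallest scale must be >= 2 * (detrend_order + 1).")
  }
  if (max(scales) > n / 4) abort("Largest scale must be <= length / 4.")
  prof <- cumsum(signal - mean(signal))
  fluct <- vapply(scales, function(s) {
    k <- n %/% s
    m <- matrix(prof[seq_len(k * s)], nrow = s)
    t_s <- seq_len(s)
    h <- stats::poly(t_s, degree = detrend_order, raw = TRUE)
    h <- cbind(1, h)
    qrh <- qr(h)
    res <- m - h %*% qr.coef(qrh, m)
    if (formulation == "rms") sqrt(mean(res^2)) else mean(abs(res))
  }, numeric(1))
  out <- list(scales = scales, fluctuation = fluct,
              detrend_order = detrend_order, formulation = formulation)
  # exactly-detrendable signals leave only rounding error: treat fluctuation
  # below machine precision relative to the profile scale as zero
  zero_tol <- 1e-12 * sqrt(mean(prof^2))
  if (any(fluct <= zero_tol) || length(scales) < 2) {
    out$alpha <- NA_real_
    out$r_squared <- NA_real_
    out$valid <- FALSE
  } else {
    fit <- lm.fit(cbind(1, log(scales)), log(fluct))
    out$alpha <- unname(coef(fit)[2])
    out$r_squared <- 1 - sum(fit$residuals^2) /
      sum((log(fluct) - mean(log(fluct)))^2)
    out$valid <- is.finite(out$alpha)
  }
  structure(out, class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha = %.3f (R^2 = %.3f, %d scales, %s, order %d)\n",
              x$alpha, x$r_squared, length(x$scales), x$formulation,
              x$detrend_order))
  invisible(x)
}

# one detrending pass per scale, both fluctuation formulations at once
# (internal; the exported dfa() is the reference implementation)
dfa_both <- function(signal, scales, detrend_order) {
  n <- length(signal)
  prof <- cumsum(signal - mean(signal))
  f_rms <- f_abs <- numeric(length(scales))
  for (i in seq_along(scales)) {
    s <- scales[i]
    k <- n %/% s
    m <- matrix(prof[seq_len(k * s)], nrow = s)
    h <- cbind(1, stats::poly(seq_len(s), degree = detrend_order, raw = TRUE))
    res <- m - h %*% qr.coef(qr(h), m)
    f_rms[i] <- sqrt(mean(res^2))
    f_abs[i] <- mean(abs(res))
  }
  zero_tol <- 1e-12 * sqrt(mean(prof^2))
  slope <- function(fl) {
    if (any(fl <= zero_tol)) return(c(NA_real_, NA_real_))
    fit <- lm.fit(cbind(1, log(scales)), log(fl))
    c(unname(coef(fit)[2]),
      1 - sum(fit$residuals^2) / sum((log(fl) - mean(log(fl)))^2))
  }
  list(rms = slope(f_rms), mean_abs = slope(f_abs))
}

#' Construct a feature matrix
#'
#' A parcels x features value matrix with a validity mask, the catalog it was
#' computed from, and a normalization state.
#'
#' @param values Numeric matrix (parcels x features) with dimnames.
#' @param catalog Tibble with columns `feature`, `family` covering the columns.
#' @param valid Logical matrix of the same shape (default: finite entries).
#' @param state `"raw"` or `"sigmoid-scaled"`.
#' @param participant Participant label (or `"group"`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, catalog = NULL, valid = NULL,
                           state = "raw", participant = "group") {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !is.null(rownames(values)))
  if (anyDuplicated(colnames(values))) abort("Duplicate feature names.")
  if (is.null(valid)) valid <- is.finite(values)
  if (is.null(catalog)) {
    catalog <- tibble(feature = colnames(values), family = "unknown")
  }
  stopifnot(all(dim(valid) == dim(values)))
  structure(list(values = values, valid = valid, catalog = catalog,
                 state = state, participant = participant),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d parcels x %d features (%s, %s); %.1f%% valid\n",
              nrow(x$values), ncol(x$values), x$state, x$participant,
              100 * mean(x$valid)))
  invisible(x)
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  vals <- as_tibble(x$values)
  vals$parcel <- rownames(x$values)
  long <- tidyr::pivot_longer(vals, -"parcel", names_to = "feature",
                              values_to = "value")
  msk <- tibble(parcel = rep(rownames(x$valid), ncol(x$valid)),
                feature = rep(colnames(x$valid), each = nrow(x$valid)),
                valid = as.vector(x$valid))
  left_join(long, msk, by = c("parcel", "feature")) %>%
    left_join(x$catalog, by = "feature")
}

#' @export
tidy.feature_matrix <- function(x, ...) as_tibble.feature_matrix(x, ...)

#' Robust sigmoid normalization of a feature matrix
#'
#' Per feature, across parcels (valid entries only): an outlier-robust
#' sigmoid `x_norm = 1 / (1 + exp(-(x - median) / (IQR / iqr_factor)))`
#' followed by a min-max rescale of the valid entries to `[0, 1]`. The
#' default `iqr_factor = 1.35` makes the sigmoid slope consistent with a
#' unit-variance Gaussian; set it to 1 for the bare-IQR convention.
#' Features with zero IQR (constant across parcels) are flagged invalid.
#'
#' @param fm A `feature_matrix` in `"raw"` state.
#' @param iqr_factor Divisor applied to the interquartile range.
#' @return A `feature_matrix` with `state = "sigmoid-scaled"`; all valid
#'   values lie in `[0, 1]`.
#' @export
normalize_feature_matrix <- function(fm, iqr_factor = 1.35) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- fm$values
  valid <- fm$valid
  for (j in seq_len(ncol(vals))) {
    ok <- valid[, j]
    if (sum(ok) < 3) {
      valid[, j] <- FALSE
      vals[, j] <- NA_real_
      next
    }
    x <- vals[ok, j]
    iqr <- stats::IQR(x) / iqr_factor
    if (iqr == 0) {
      valid[, j] <- FALSE
      vals[, j] <- NA_real_
      next
    }
    xn <- 1 / (1 + exp(-(x - median(x)) / iqr))
    rng <- range(xn)
    vals[ok, j] <- if (diff(rng) == 0) 0.5 else (xn - rng[1]) / diff(rng)
    vals[!ok, j] <- NA_real_
  }
  feature_matrix(vals, fm$catalog, valid, state = "sigmoid-scaled",
                 participant = fm$participant)
}

#' Group-average feature matrix across participants
#'
#' Features with any invalid entry in any participant are dropped globally
#' (error-producing operations are removed before averaging); the remaining
#' entries are averaged across participants.
#'
#' @param fm_list List of `feature_matrix` objects sharing parcels and
#'   catalog.
#' @return A group-level `feature_matrix`.
#' @export
aggregate_group <- function(fm_list) {
  stopifnot(length(fm_list) >= 1,
            all(purrr::map_lgl(fm_list, inherits, "feature_matrix")))
  feats <- colnames(fm_list[[1]]$values)
  parcels <- rownames(fm_list[[1]]$values)
  for (fm in fm_list) {
    if (!identical(colnames(fm$values), feats) ||
        !identical(rownames(fm$values), parcels)) {
      abort("Feature matrices must share parcels and catalog.")
    }
  }
  all_valid <- Reduce(`&`, purrr::map(fm_list, function(fm) {
    apply(fm$valid, 2, all)
  }))
  if (!any(all_valid)) abort("No feature is valid in every participant.")
  keep <- feats[all_valid]
  avg <- Reduce(`+`, purrr::map(fm_list, function(fm) {
    fm$values[, keep, drop = FALSE]
  })) / length(fm_list)
  feature_matrix(avg,
                 fm_list[[1]]$catalog %>% filter(.data$feature %in% keep),
                 state = fm_list[[1]]$state, participant = "group")
}

#' Feature stability across segment lengths
#'
#' Extracts a reduced, fast feature set from nested-from-start segments of
#' increasing length and reports the Pearson correlation between the feature
#' vectors of consecutive lengths — the curve used to judge how much data is
#' needed before features stabilize.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param lengths_s Segment lengths in seconds (default 5 to 125 by 5);
#'   lengths beyond the available signal are dropped with a warning.
#' @param catalog Feature catalog; defaults to [reduced_catalog()].
#' @return Tibble with `length_s` (the longer segment of each pair) and `r`
#'   (`NA` when either feature vector is constant).
#' @export
stability_curve <- function(signal, fs, lengths_s = seq(5, 125, by = 5),
                            catalog = reduced_catalog()) {
  n <- length(signal)
  lengths_s <- sort(lengths_s)
  usable <- lengths_s[round(lengths_s * fs) <= n]
  if (length(usable) < length(lengths_s)) {
    warn("Signal shorter than requested lengths; curve truncated.")
  }
  usable <- usable[round(usable * fs) >= 256]
  if (length(usable) < 2) abort("Fewer than 2 segment lengths evaluable.")
  vecs <- purrr::map(usable, function(ls) {
    fv <- compute_feature_vector(signal[seq_len(round(ls * fs))], fs,
                                 catalog = catalog)
    setNames(ifelse(fv$valid, fv$value, NA_real_), fv$feature)
  })
  purrr::map_dfr(seq_len(length(usable) - 1), function(i) {
    a <- vecs[[i]]; b <- vecs[[i + 1]]
    ok <- is.finite(a) & is.finite(b)
    r <- if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      NA_real_
    } else {
      cor(a[ok], b[ok])
    }
    tibble(length_s = usable[i + 1], r = r)
  })
}
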