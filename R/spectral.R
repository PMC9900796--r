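#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over Hann-tapered, overlapping windows,
#' returned as a one-sided spectral density so that the integral over
#' `[0, fs/2]` equals the signal variance.
#'
#' @param ts A `regional_ts` object, a numeric matrix (regions x samples), or
#'   a numeric vector. For matrices/vectors `fs` must be given.
#' @param window_s Window length in seconds (default 4 s).
#' @param overlap Fractional window overlap (default 0.5).
#' @param fs Sampling rate in Hz (taken from `ts` when it is a `regional_ts`).
#' @param participant Which participant of a `regional_ts` to use (default 1).
#' @return An object of class `psd_estimate`: list with `freq` (Hz),
#'   `power` (regions x frequencies, one-sided density), `fs`, `window_s`,
#'   `overlap`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 8, by = 1 / 256))
#' p <- welch_psd(x, fs = 256)
#' p$freq[which.max(p$power[1, ])]
#' @export
welch_psd <- function(ts, window_s = 4, overlap = 0.5, fs = NULL,
                      participant = 1L) {
  if (inherits(ts, "regional_ts")) {
    fs <- ts$fs
    x <- ts$data[[participant]]
  } else if (is.matrix(ts)) {
    x <- ts
  } else {
    x <- matrix(ts, nrow = 1)
  }
  if (is.null(fs)) abort("`fs` must be supplied for matrix/vector input.")
  nw <- round(window_s * fs)
  n <- ncol(x)
  if (nw > n) abort("Window longer than signal.")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, n - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1)) # Hann taper
  u <- sum(w^2)
  n_half <- floor(nw / 2)
  scale <- 1 / (fs * u)
  acc <- matrix(0, nrow(x), n_half + 1)
  for (s in starts) {
    seg <- x[, s:(s + nw - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    ft <- t(apply(seg, 1, fft))
    if (nrow(x) == 1) ft <- matrix(ft, nrow = 1)
    pxx <- Mod(ft[, seq_len(n_half + 1), drop = FALSE])^2 * scale
    # double non-DC, non-Nyquist bins for the one-sided convention
    dbl <- 2:(n_half + if (nw %% 2 == 0) 0 else 1)
    pxx[, dbl] <- 2 * pxx[, dbl]
    acc <- acc + pxx
  }
  power <- acc / length(starts)
  rownames(power) <- rownames(x)
  structure(
    list(freq = (0:n_half) * fs / nw, power = power, fs = fs,
         window_s = window_s, overlap = overlap),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d region(s), %d bins, df = %.3g Hz\n",
              nrow(x$power), length(x$freq), diff(x$freq[1:2])))
  invisible(x)
}

#' Canonical electrophysiological frequency bands
#'
#' Total-power bands: delta 2-4, theta 5-7, alpha 8-12, beta 15-29,
#' lo_gamma 30-59, hi_gamma 60-90 Hz. Aperiodic-adjusted bands (used for
#' oscillation scores, gamma excluded): delta 2-4, theta 5-7, alpha 8-14,
#' beta 15-30 Hz.
#'
#' @param adjusted If `TRUE` return the 4 aperiodic-adjusted bands.
#' @return Tibble with columns `band`, `lo`, `hi` (Hz, inclusive).
#' @export
canonical_bands <- function(adjusted = FALSE) {
  if (adjusted) {
    tibble(band = c("delta", "theta", "alpha", "beta"),
           lo = c(2, 5, 8, 15), hi = c(4, 7, 14, 30))
  } else {
    tibble(band = c("delta", "theta", "alpha", "beta", "lo_gamma", "hi_gamma"),
           lo = c(2, 5, 8, 15, 30, 60), hi = c(4, 7, 12, 29, 59, 90))
  }
}

#' Mean band power from a PSD estimate
#'
#' Arithmetic mean of the spectral density over the frequency bins inside
#' each band (inclusive bounds).
#'
#' @param psd A `psd_estimate`.
#' @param bands Tibble with columns `band`, `lo`, `hi`; defaults to the six
#'   canonical bands.
#' @return Tibble with columns `parcel`, `band`, `power`.
#' @export
band_power <- function(psd, bands = canonical_bands()) {
  stopifnot(inherits(psd, "psd_estimate"))
  parcels <- rownames(psd$power)
  if (is.null(parcels)) parcels <- sprintf("r%03d", seq_len(nrow(psd$power)))
  purrr::pmap_dfr(bands, function(band, lo, hi) {
    sel <- psd$freq >= lo & psd$freq <= hi
    if (!any(sel)) abort(sprintf("Band %s [%g, %g] outside frequency grid.",
                                 band, lo, hi))
    tibble(parcel = parcels, band = band,
           power = unname(rowMeans(psd$power[, sel, drop = FALSE])))
  })
}

gaussian_sum <- function(f, centers, heights, sds) {
  y <- numeric(length(f))
  for (i in seq_along(centers)) {
    y <- y + heights[i] * exp(-(f - centers[i])^2 / (2 * sds[i]^2))
  }
  y
}

# bounded NLS of the aperiodic knee model in log10-power space,
# multi-start over the exponent to escape local minima; `warm` supplies a
# single additional start (used by the refit passes)
fit_aperiodic <- function(f, y, chi_starts = c(0.5, 1.5, 2.5), warm = NULL) {
  obj <- function(par) {
    r <- y - (par[1] - log10(10^par[2] + f^par[3]))
    sum(r^2)
  }
  grad <- function(par) {
    k10 <- 10^par[2]
    fx <- f^par[3]
    u <- k10 + fx
    r <- y - (par[1] - log10(u))
    c(-2 * sum(r),
      2 * sum(r * k10 / u),
      2 * sum(r * fx * log(f) / u) / log(10))
  }
  starts <- if (is.null(warm)) {
    lapply(chi_starts, function(chi0) {
      lk0 <- log10(stats::median(f)^chi0)
      c(y[1] + log10(10^lk0 + f[1]^chi0), lk0, chi0)
    })
  } else {
    # refit passes refine the existing solution; multi-start already happened
    list(unname(c(warm["offset"], log10(warm["knee"]), warm["exponent"])))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, obj, grad, method = "L-BFGS-B",
            lower = c(-50, -6, 0.05), upper = c(50, 9, 8),
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  c(offset = best$par[1], knee = 10^best$par[2], exponent = best$par[3])
}

fit_one_spectrum <- function(f, pwr, peak_width_limits, max_n_peaks,
                             min_peak_height, peak_threshold) {
  y <- log10(pwr)
  empty_peaks <- tibble(center = numeric(), height = numeric(),
                        width = numeric())
  failed <- list(offset = NA_real_, knee = NA_real_, exponent = NA_real_,
                 r_squared = NA_real_, peaks = empty_peaks)
  ap <- fit_aperiodic(f, y)
  if (is.null(ap)) return(failed)
  # robust refit: clip the flattened spectrum at zero and keep the points not
  # sitting above the initial fit (oscillatory peaks are excluded this way)
  flat <- y - (ap["offset"] - log10(ap["knee"] + f^ap["exponent"]))
  flat[flat < 0] <- 0
  keep <- flat <= quantile(flat, 0.025)
  if (sum(keep) >= 5) {
    ap2 <- fit_aperiodic(f[keep], y[keep], warm = ap)
    if (!is.null(ap2)) ap <- ap2
  }
  flatspec <- y - (ap["offset"] - log10(ap["knee"] + f^ap["exponent"]))
  sd_limits <- peak_width_limits / 2
  # iterative guess extraction, largest residual first
  resid <- flatspec
  guesses <- list()
  while (length(guesses) < max_n_peaks) {
    imax <- which.max(resid)
    h <- resid[imax]
    if (!is.finite(h) || h <= peak_threshold * sd(resid) ||
        h <= min_peak_height) {
      break
    }
    cf <- f[imax]
    half <- h / 2
    ri <- which(resid[imax:length(resid)] <= half)
    li <- which(resid[imax:1] <= half)
    half_w <- min(if (length(ri)) f[imax + ri[1] - 1] - cf else Inf,
                  if (length(li)) cf - f[imax - li[1] + 1] else Inf)
    # half-width at half maximum -> Gaussian sd
    sd_guess <- if (is.finite(half_w) && half_w > 0) {
      half_w / sqrt(2 * log(2))
    } else {
      mean(sd_limits)
    }
    sd_guess <- min(max(sd_guess, sd_limits[1]), sd_limits[2])
    guesses[[length(guesses) + 1]] <- c(cf, h, sd_guess)
    resid <- resid - h * exp(-(f - cf)^2 / (2 * sd_guess^2))
  }
  if (length(guesses) > 0) {
    g0 <- do.call(rbind, guesses)
    # guard rails: drop guesses hugging the fit-range edges (one standard
    # deviation), then resolve overlapping guesses by keeping the taller
    edge_ok <- (g0[, 1] - min(f)) >= g0[, 3] & (max(f) - g0[, 1]) >= g0[, 3]
    g0 <- g0[edge_ok, , drop = FALSE]
    if (nrow(g0) > 1) {
      ord <- order(g0[, 1])
      g0 <- g0[ord, , drop = FALSE]
      drop <- rep(FALSE, nrow(g0))
      for (i in seq_len(nrow(g0) - 1)) {
        if (g0[i + 1, 1] - g0[i, 1] < 0.75 * (g0[i, 3] + g0[i + 1, 3])) {
          smaller <- if (g0[i, 2] < g0[i + 1, 2]) i else i + 1
          drop[smaller] <- TRUE
        }
      }
      g0 <- g0[!drop, , drop = FALSE]
    }
    guesses <- lapply(seq_len(nrow(g0)), function(i) g0[i, ])
  }
  peaks <- empty_peaks
  if (length(guesses) > 0) {
    g <- do.call(rbind, guesses)
    np <- nrow(g)
    par0 <- as.vector(t(g))
    obj <- function(par) {
      p <- matrix(par, ncol = 3, byrow = TRUE)
      sum((flatspec - gaussian_sum(f, p[, 1], p[, 2], p[, 3]))^2)
    }
    grad <- function(par) {
      p <- matrix(par, ncol = 3, byrow = TRUE)
      gs <- lapply(seq_len(nrow(p)), function(i) {
        exp(-(f - p[i, 1])^2 / (2 * p[i, 3]^2))
      })
      model <- numeric(length(f))
      for (i in seq_len(nrow(p))) model <- model + p[i, 2] * gs[[i]]
      r <- flatspec - model
      out <- numeric(length(par))
      for (i in seq_len(nrow(p))) {
        d <- f - p[i, 1]
        out[3 * i - 2] <- -2 * sum(r * p[i, 2] * gs[[i]] * d / p[i, 3]^2)
        out[3 * i - 1] <- -2 * sum(r * gs[[i]])
        out[3 * i] <- -2 * sum(r * p[i, 2] * gs[[i]] * d^2 / p[i, 3]^3)
      }
      out
    }
    lower <- as.vector(t(cbind(pmax(min(f), g[, 1] - 2 * g[, 3]), 0,
                               sd_limits[1])))
    upper <- as.vector(t(cbind(pmin(max(f), g[, 1] + 2 * g[, 3]), Inf,
                               sd_limits[2])))
    refit <- tryCatch(
      optim(par0, obj, grad, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 500)),
      error = function(e) NULL
    )
    p <- matrix(if (is.null(refit)) par0 else refit$par, ncol = 3,
                byrow = TRUE)
    ok <- is.finite(p[, 2]) & p[, 2] >= min_peak_height
    peaks <- tibble(center = p[ok, 1], height = p[ok, 2], width = p[ok, 3])
    peaks <- arrange(peaks, dplyr::desc(.data$height))
  }
  # joint step: refit the aperiodic component on the peak-removed spectrum
  y_ap <- y - gaussian_sum(f, peaks$center, peaks$height, peaks$width)
  ap3 <- fit_aperiodic(f, y_ap, warm = ap)
  if (!is.null(ap3)) ap <- ap3
  model <- (ap["offset"] - log10(ap["knee"] + f^ap["exponent"])) +
    gaussian_sum(f, peaks$center, peaks$height, peaks$width)
  r2 <- suppressWarnings(cor(y, model)^2)
  list(offset = unname(ap["offset"]), knee = unname(ap["knee"]),
       exponent = unname(ap["exponent"]), r_squared = unname(r2),
       peaks = peaks)
}

#' Parameterize power spectra into aperiodic and oscillatory components
#'
#' Fits, per region and in log10-power space, the spectral model
#' `log10 PSD(f) = b - log10(k + f^chi) + sum of Gaussian peaks`: (1) a robust
#' multi-start bounded least-squares fit of the aperiodic knee component,
#' excluding points lying above the initial fit; (2) Gaussian peaks extracted
#' from the flattened residual largest-first until `max_n_peaks` is reached or
#' no residual exceeds both `peak_threshold` residual standard deviations and
#' `min_peak_height`, followed by a joint refit of all peaks; (3) a final
#' aperiodic refit on the peak-removed spectrum. R-squared of the full model
#' against the log spectrum is reported.
#'
#' @param psd A `psd_estimate`.
#' @param fit_lo,fit_hi Fit range in Hz (defaults 1-60).
#' @param peak_width_limits Bounds on peak width in Hz (full width; Gaussian
#'   standard deviations are bounded by half these values), default `c(1, 6)`.
#' @param max_n_peaks Maximum number of peaks (default 6).
#' @param min_peak_height Minimum peak height in log10-power (default 0.1).
#' @param peak_threshold Peak detection threshold in residual standard
#'   deviations (default 2).
#' @return An object of class `spectral_fit`: list with tibbles `aperiodic`
#'   (`parcel`, `offset`, `knee`, `exponent`, `r_squared`, `n_peaks`) and
#'   `peaks` (`parcel`, `center`, `height`, `width`), plus the fit settings.
#' @export
fit_spectral_model <- function(psd, fit_lo = 1, fit_hi = 60,
                               peak_width_limits = c(1, 6), max_n_peaks = 6,
                               min_peak_height = 0.1, peak_threshold = 2.0) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (fit_lo <= 0) abort("`fit_lo` must be > 0 (log-frequency fit).")
  sel <- psd$freq >= fit_lo & psd$freq <= fit_hi
  if (sum(sel) < 8) abort("Too few frequency bins in fit range.")
  f <- psd$freq[sel]
  parcels <- rownames(psd$power)
  if (is.null(parcels)) parcels <- sprintf("r%03d", seq_len(nrow(psd$power)))
  rows <- vector("list", nrow(psd$power))
  pk <- vector("list", nrow(psd$power))
  for (i in seq_len(nrow(psd$power))) {
    pw <- psd$power[i, sel]
    if (any(pw <= 0)) abort("PSD must be strictly positive on the fit range.")
    fit <- fit_one_spectrum(f, pw, peak_width_limits, max_n_peaks,
                            min_peak_height, peak_threshold)
    rows[[i]] <- tibble(parcel = parcels[i], offset = fit$offset,
                        knee = fit$knee, exponent = fit$exponent,
                        r_squared = fit$r_squared,
                        n_peaks = nrow(fit$peaks))
    if (nrow(fit$peaks) > 0) {
      pk[[i]] <- bind_cols(tibble(parcel = parcels[i]), fit$peaks)
    }
  }
  structure(
    list(aperiodic = bind_rows(rows), peaks = bind_rows(pk),
         fit_range = c(fit_lo, fit_hi),
         settings = list(peak_width_limits = peak_width_limits,
                         max_n_peaks = max_n_peaks,
                         min_peak_height = min_peak_height,
                         peak_threshold = peak_threshold)),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> %d region(s), %d peak(s), fit range %g-%g Hz\n",
              nrow(x$aperiodic), nrow(x$peaks), x$fit_range[1],
              x$fit_range[2]))
  invisible(x)
}

#' Knee frequency and intrinsic timescale from an aperiodic fit
#'
#' The knee parameter `k` and exponent `chi` of the aperiodic component give
#' the knee frequency `f_k = k^(1/chi)` (where the spectrum bends) and the
#' intrinsic timescale `tau = 1 / (2 * pi * f_k)` in seconds.
#'
#' @param fit A `spectral_fit`, or a data frame with columns `knee` and
#'   `exponent` (and optionally `parcel`).
#' @return Tibble with columns `parcel`, `knee`, `exponent`, `knee_freq`
#'   (Hz), `tau` (s), `valid` (FALSE where `k <= 0` or `chi <= 0`, in which
#'   case the timescale is undefined and reported as `NA`).
#' @examples
#' knee_timescale(data.frame(knee = 100, exponent = 2))
#' @export
knee_timescale <- function(fit) {
  ap <- if (inherits(fit, "spectral_fit")) fit$aperiodic else as_tibble(fit)
  if (!all(c("knee", "exponent") %in% names(ap))) {
    abort("Need columns `knee` and `exponent`.")
  }
  if (!"parcel" %in% names(ap)) ap$parcel <- sprintf("r%03d", seq_len(nrow(ap)))
  valid <- is.finite(ap$knee) & is.finite(ap$exponent) &
    ap$knee > 0 & ap$exponent > 0
  fk <- ifelse(valid, ap$knee^(1 / ap$exponent), NA_real_)
  tibble(parcel = ap$parcel, knee = ap$knee, exponent = ap$exponent,
         knee_freq = fk, tau = 1 / (2 * pi * fk), valid = valid)
}

#' Band-limited oscillation scores across participants
#'
#' For each frequency band and parcel: take, per participant, the detected
#' peak with maximum power in the band (if any); average peak power over the
#' participants with a detection; normalize the group-average power map by its
#' maximum across parcels; multiply by the detection-probability map (fraction
#' of participants with at least one in-band peak). Gamma bands are excluded
#' by default because consistent spectral peaks are not detectable there.
#'
#' @param fits A list of `spectral_fit` objects, one per participant.
#' @param bands Band tibble; defaults to the 4 aperiodic-adjusted bands.
#' @return Tibble with columns `band`, `parcel`, `mean_power`, `norm_power`,
#'   `probability`, `score` (`score = norm_power * probability`, in `[0, 1]`).
#' @export
oscillation_score <- function(fits, bands = canonical_bands(adjusted = TRUE)) {
  if (inherits(fits, "spectral_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  parcels <- fits[[1]]$aperiodic$parcel
  n_sub <- length(fits)
  purrr::pmap_dfr(bands, function(band, lo, hi) {
    pow <- matrix(NA_real_, length(parcels), n_sub,
                  dimnames = list(parcels, NULL))
    for (s in seq_len(n_sub)) {
      pks <- fits[[s]]$peaks
      if (nrow(pks) == 0) next
      keep <- is.finite(pks$center) & is.finite(pks$height) &
        pks$center >= lo & pks$center <= hi
      if (!any(keep)) next
      best <- tapply(pks$height[keep], pks$parcel[keep], max)
      pow[names(best), s] <- as.vector(best)
    }
    detected <- !is.na(pow)
    probability <- rowMeans(detected)
    mean_power <- ifelse(rowSums(detected) > 0,
                         rowMeans(pow, na.rm = TRUE), NA_real_)
    if (all(is.na(mean_power))) {
      warn(sprintf("No peaks detected in band %s; scores all zero.", band))
      norm_power <- rep(0, length(parcels))
    } else {
      norm_power <- mean_power / max(mean_power, na.rm = TRUE)
      norm_power[is.na(norm_power)] <- 0
    }
    tibble(band = band, parcel = parcels, mean_power = unname(mean_power),
           norm_power = unname(norm_power), probability = unname(probability),
           score = unname(norm_power * probability))
  })
}
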