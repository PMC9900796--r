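#' Generate a mirrored spherical parcellation geometry
#'
#' Builds `2 * n_per_hemisphere` parcel centroids on the unit sphere: the left
#' hemisphere (x < 0) is a quasi-uniform Fibonacci lattice and the right
#' hemisphere is its mirror image through the x = 0 plane, emulating the
#' centroid geometry of a bilateral cortical atlas (one centroid per parcel,
#' no surface mesh).
#'
#' @param n_per_hemisphere Number of parcels per hemisphere (>= 2).
#' @param seed Integer seed; accepted for interface uniformity (the lattice is
#'   deterministic) and recorded in the output.
#' @return A tibble of class `parcellation` with columns `parcel`, `hemi`
#'   (`"L"`/`"R"`) and unit-norm centroid coordinates `x`, `y`, `z`.
#' @examples
#' geom <- gen_parcellation(50)
#' range(sqrt(geom$x^2 + geom$y^2 + geom$z^2))
#' @export
gen_parcellation <- function(n_per_hemisphere, seed = 1L) {
  if (!is.numeric(n_per_hemisphere) || n_per_hemisphere < 2) {
    abort("`n_per_hemisphere` must be >= 2.")
  }
  n <- as.integer(n_per_hemisphere)
  i <- seq_len(n)
  # Fibonacci lattice on the open hemisphere: depth into the hemisphere in
  # (0, 1), golden-angle winding around the x axis keeps points quasi-uniform
  depth <- (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - depth^2))
  left <- cbind(x = -depth, y = r * cos(phi), z = r * sin(phi))
  right <- left
  right[, "x"] <- -right[, "x"]
  geom <- tibble(
    parcel = c(sprintf("L_%03d", i), sprintf("R_%03d", i)),
    hemi = rep(c("L", "R"), each = n),
    x = c(left[, "x"], right[, "x"]),
    y = c(left[, "y"], right[, "y"]),
    z = c(left[, "z"], right[, "z"])
  )
  attr(geom, "seed") <- as.integer(seed)
  class(geom) <- c("parcellation", class(geom))
  geom
}

# centroids as an n x 3 matrix, rows named by parcel
centroid_matrix <- function(geometry) {
  stopifnot(all(c("parcel", "x", "y", "z") %in% names(geometry)))
  m <- as.matrix(geometry[, c("x", "y", "z")])
  rownames(m) <- geometry$parcel
  m
}

# great-circle (angular) distance matrix between unit vectors
angular_distance <- function(a, b = a) {
  d <- tcrossprod(a, b)
  acos(pmin(pmax(d, -1), 1)) # matrix first: pmin/pmax keep its dim
}

#' Draw a spatially autocorrelated map on a parcellation
#'
#' Samples one realization of a zero-mean Gaussian process on the sphere with
#' squared-exponential covariance in great-circle distance, then standardizes
#' it to zero mean and unit variance across parcels. Used both as the latent
#' spatial factor behind coupled synthetic datasets and as the calibration
#' input for spatial-autocorrelation-preserving null models.
#'
#' @param geometry A `parcellation` tibble from [gen_parcellation()].
#' @param lengthscale Correlation length in radians of great-circle distance
#'   (> 0); small values approach parcel-wise independence, large values a
#'   near-constant map.
#' @param seed Integer seed.
#' @param n_maps Number of independent maps to draw (columns of the result).
#' @param standardize Standardize each draw to zero mean and unit variance
#'   across parcels (default). Set to `FALSE` to keep the raw process scale,
#'   e.g. when studying the lengthscale limits (a very long lengthscale gives
#'   a near-constant map whose across-parcel variance vanishes — a property
#'   standardization would hide).
#' @return A numeric vector (or, for `n_maps > 1`, a matrix with parcels in
#'   rows) named by parcel.
#' @examples
#' geom <- gen_parcellation(20)
#' m <- gen_smooth_map(geom, lengthscale = 0.5, seed = 1)
#' round(c(mean(m), sd(m)), 10)
#' @export
gen_smooth_map <- function(geometry, lengthscale = 0.5, seed = 1L,
                           n_maps = 1L, standardize = TRUE) {
  if (!is.numeric(lengthscale) || lengthscale <= 0) {
    abort("`lengthscale` must be > 0.")
  }
  cm <- centroid_matrix(geometry)
  d <- angular_distance(cm)
  k <- exp(-0.5 * (d / lengthscale)^2)
  l <- NULL
  jitter <- 1e-10
  for (try in 1:8) {
    l <- tryCatch(chol(k + diag(jitter, nrow(k))), error = function(e) NULL)
    if (!is.null(l)) break
    jitter <- jitter * 100
  }
  if (is.null(l)) abort("Covariance not positive definite after jitter.")
  draws <- with_seed(seed, matrix(rnorm(nrow(k) * n_maps), nrow(k), n_maps))
  maps <- crossprod(l, draws)
  if (standardize) {
    maps <- scale(maps)[, , drop = FALSE] # zero mean, unit variance per draw
  }
  rownames(maps) <- geometry$parcel
  if (n_maps == 1L) maps[, 1] else maps
}

#' Linearly graded spectral profiles along a latent map
#'
#' Convenience constructor for the per-parcel aperiodic and oscillatory-peak
#' parameter tables consumed by [gen_regional_timeseries()]. Parameters vary
#' linearly with a latent map rescaled to `[0, 1]`: the knee frequency, peak
#' amplitude and peak frequency all increase along the gradient, emulating a
#' unimodal-to-transmodal hierarchy of spectra.
#'
#' @param geometry A `parcellation` tibble.
#' @param latent Per-parcel latent values (any scale; only ranks of the linear
#'   rescale matter).
#' @param knee_freq_range Knee frequency at the two gradient extremes (Hz).
#' @param exponent Aperiodic exponent chi (recycled per parcel).
#' @param offset Aperiodic offset b in log10-power units.
#' @param peak_freq_range Alpha-like peak center at the extremes (Hz).
#' @param peak_height_range Peak height at the extremes (log10-power).
#' @param peak_width Peak Gaussian width (Hz, standard deviation).
#' @return A list with tibbles `aperiodic` (parcel, offset, knee, exponent)
#'   and `peaks` (parcel, center, height, width).
#' @export
graded_profiles <- function(geometry, latent,
                            knee_freq_range = c(3, 12),
                            exponent = 2,
                            offset = 0,
                            peak_freq_range = c(8, 12),
                            peak_height_range = c(0.2, 0.8),
                            peak_width = 1.5) {
  u <- (latent - min(latent)) / (max(latent) - min(latent))
  fk <- knee_freq_range[1] + u * diff(knee_freq_range)
  list(
    aperiodic = tibble(
      parcel = geometry$parcel,
      offset = rep_len(offset, nrow(geometry)),
      knee = fk^rep_len(exponent, nrow(geometry)),
      exponent = rep_len(exponent, nrow(geometry))
    ),
    peaks = tibble(
      parcel = geometry$parcel,
      center = peak_freq_range[1] + u * diff(peak_freq_range),
      height = peak_height_range[1] + u * diff(peak_height_range),
      width = rep_len(peak_width, nrow(geometry))
    )
  )
}

# target one-sided log10 PSD of the generator/fit model at frequencies f
model_log_psd <- function(f, offset, knee, exponent, peaks = NULL) {
  y <- offset - log10(knee + f^exponent)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    for (r in seq_len(nrow(peaks))) {
      y <- y + peaks$height[r] *
        exp(-(f - peaks$center[r])^2 / (2 * peaks$width[r]^2))
    }
  }
  y
}

# one realization of spectrally shaped Gaussian noise with one-sided target
# density 10^log_psd(f); exact target PSD in expectation
shape_noise <- function(n, fs, log_psd_fun) {
  stopifnot(n >= 4)
  n_half <- floor(n / 2)
  f <- seq_len(n_half) * fs / n
  s <- 10^log_psd_fun(f)
  amp <- sqrt(n * fs * s / 2)
  re <- rnorm(n_half)
  im <- rnorm(n_half)
  spec <- complex(real = amp * re / sqrt(2), imaginary = amp * im / sqrt(2))
  if (n %% 2 == 0) { # Nyquist bin is real
    spec[n_half] <- complex(real = amp[n_half] * re[n_half], imaginary = 0)
  }
  full <- complex(length.out = n)
  full[2:(n_half + 1)] <- spec
  n_neg <- if (n %% 2 == 0) n_half - 1L else n_half
  full[seq(n, n - n_neg + 1)] <- Conj(spec[seq_len(n_neg)])
  x <- Re(fft(full, inverse = TRUE)) / n
  x - mean(x)
}

#' Generate regional neurophysiological time-series with known spectra
#'
#' Each region's signal is spectrally shaped Gaussian noise whose one-sided
#' power spectral density follows the periodic + aperiodic model
#' `log10 PSD(f) = b - log10(k + f^chi) + sum of Gaussian peaks`, i.e. a
#' 1/f-with-knee background plus band-limited oscillations. Shaping is exact
#' in expectation (frequency-domain amplitude modulation of white noise), so
#' the spectral analysis module can be validated against the generating
#' parameters. Signals are standardized to zero mean.
#'
#' @param geometry A `parcellation` tibble.
#' @param duration_s Recording length in seconds.
#' @param fs_hz Sampling rate in Hz.
#' @param aperiodic_profile Tibble with columns `parcel`, `offset`, `knee`,
#'   `exponent` (one row per parcel; `knee`, `exponent` > 0).
#' @param peak_profile Optional tibble with columns `parcel`, `center`,
#'   `height`, `width` (possibly several rows per parcel); `NULL` for no
#'   oscillatory peaks.
#' @param seed Integer seed.
#' @param n_participants Number of independent participant realizations.
#' @param participant_jitter Fractional log-normal jitter applied to each
#'   participant's knee and peak-height parameters (0 = identical spectra;
#'   inter-participant spectral variability is not characterized empirically,
#'   so this is an exposed knob, not a fidelity claim).
#' @return An object of class `regional_ts`: a list with `data` (list of
#'   participant matrices, parcels x samples), `fs`, `parcel`, and the
#'   generating profiles.
#' @export
gen_regional_timeseries <- function(geometry, duration_s, fs_hz,
                                    aperiodic_profile, peak_profile = NULL,
                                    seed = 1L, n_participants = 1L,
                                    participant_jitter = 0) {
  n <- round(duration_s * fs_hz)
  if (n < 2 * fs_hz) abort("Need at least 2 seconds of signal.")
  if (any(aperiodic_profile$knee <= 0) || any(aperiodic_profile$exponent <= 0)) {
    abort("Aperiodic profile requires knee > 0 and exponent > 0.")
  }
  if (!is.null(peak_profile) && nrow(peak_profile) > 0 &&
      any(peak_profile$center + 2 * peak_profile$width >= fs_hz / 2)) {
    abort("Peak frequency too close to Nyquist for this sampling rate.")
  }
  ap <- aperiodic_profile[match(geometry$parcel, aperiodic_profile$parcel), ]
  if (anyNA(ap$knee)) abort("Aperiodic profile missing parcels.")
  data <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    pseed <- split_seed(seed, paste0("participant-", p))
    data[[p]] <- with_seed(pseed, {
      jit_k <- exp(rnorm(nrow(ap), 0, participant_jitter))
      jit_h <- exp(rnorm(nrow(ap), 0, participant_jitter))
      out <- matrix(0, nrow(ap), n,
                    dimnames = list(geometry$parcel, NULL))
      for (i in seq_len(nrow(ap))) {
        pk <- NULL
        if (!is.null(peak_profile)) {
          pk <- peak_profile[peak_profile$parcel == geometry$parcel[i], ]
          if (nrow(pk) > 0) pk$height <- pk$height * jit_h[i]
        }
        off <- ap$offset[i]; kn <- ap$knee[i] * jit_k[i]; ex <- ap$exponent[i]
        out[i, ] <- shape_noise(n, fs_hz, function(f) {
          model_log_psd(f, off, kn, ex, pk)
        })
      }
      out
    })
  }
  structure(
    list(data = data, fs = fs_hz, parcel = geometry$parcel,
         aperiodic = ap, peaks = peak_profile, seed = as.integer(seed)),
    class = "regional_ts"
  )
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf(
    "<regional_ts> %d participant(s), %d parcels x %d samples at %g Hz\n",
    length(x$data), nrow(x$data[[1]]), ncol(x$data[[1]]), x$fs
  ))
  invisible(x)
}

#' Generate coupled time-series-feature and micro-architecture datasets
#'
#' Builds a rank-1 latent model for partial-least-squares parameter recovery:
#' a smooth latent map `z` on the parcellation drives both a parcels x
#' features matrix `X = coupling * z w_x' + noise` and a parcels x maps
#' matrix `Y = coupling * z w_y' + noise`, with unit-norm weight vectors and
#' independent Gaussian noise. The ground truth is returned so recovery of
#' weights and latent structure can be asserted.
#'
#' @param geometry A `parcellation` tibble.
#' @param n_ts_features,n_micro_features Numbers of columns of X and Y (>= 1).
#' @param coupling_strength Shared-signal scale in `[0, 1]`.
#' @param noise_sd Independent noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param lengthscale Latent-map correlation length (radians).
#' @return A list of class `coupled_sets` with matrices `x`, `y` (parcel rows)
#'   and `truth` (latent map, unit-norm `ts_weights`, `micro_weights`,
#'   `coupling`, `noise_sd`, `seed`).
#' @export
gen_coupled_feature_sets <- function(geometry, n_ts_features, n_micro_features,
                                     coupling_strength = 0.9, noise_sd = 0.5,
                                     seed = 1L, lengthscale = 0.5) {
  if (n_ts_features < 1 || n_micro_features < 1) {
    abort("Feature counts must be >= 1.")
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    abort("`coupling_strength` must be in [0, 1].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  z <- gen_smooth_map(geometry, lengthscale, split_seed(seed, "latent"))
  np <- nrow(geometry)
  out <- with_seed(split_seed(seed, "coupled"), {
    wx <- rnorm(n_ts_features); wx <- wx / sqrt(sum(wx^2))
    wy <- rnorm(n_micro_features); wy <- wy / sqrt(sum(wy^2))
    x <- coupling_strength * tcrossprod(z, wx) +
      noise_sd * matrix(rnorm(np * n_ts_features), np)
    y <- coupling_strength * tcrossprod(z, wy) +
      noise_sd * matrix(rnorm(np * n_micro_features), np)
    list(wx = wx, wy = wy, x = x, y = y)
  })
  dimnames(out$x) <- list(geometry$parcel,
                          sprintf("ts_f%03d", seq_len(n_ts_features)))
  dimnames(out$y) <- list(geometry$parcel,
                          sprintf("micro_%02d", seq_len(n_micro_features)))
  structure(
    list(
      x = out$x, y = out$y,
      truth = list(latent_map = z, ts_weights = out$wx,
                   micro_weights = out$wy, coupling = coupling_strength,
                   noise_sd = noise_sd, seed = as.integer(seed))
    ),
    class = "coupled_sets"
  )
}

#' Generate multi-donor probe-level expression tables
#'
#' Emulates Allen-Human-Brain-Atlas-style microarray data: each probe has one
#' shared regional expression profile, observed per donor as
#' `reliability * profile + (1 - reliability) * donor noise`, plus per-sample
#' below-background flags (a subset of probes is made intentionally weak so
#' the intensity filter has something to remove). Probes map many-to-one onto
#' genes. One tissue sample per region per donor; if a geometry is supplied,
#' samples receive jittered centroid coordinates for the assignment stage.
#'
#' @param n_donors Number of donors (>= 2).
#' @param n_regions Number of regions (>= 3; ranks need room).
#' @param n_probes Number of probes.
#' @param reliability Cross-donor profile consistency in `[0, 1]`.
#' @param seed Integer seed.
#' @param geometry Optional `parcellation` with `n_regions` parcels used to
#'   attach sample coordinates.
#' @param coord_jitter Angular jitter (radians) of sample coordinates.
#' @param weak_fraction Fraction of probes given high below-background rates.
#' @return A list of class `donor_expression`: `probes` (tibble probe, gene),
#'   per-donor `expr` (probe x sample matrices), `background` (logical, TRUE =
#'   below background), `samples` (tibbles with sample, region and optional
#'   coordinates), and the generating parameters.
#' @export
gen_donor_expression <- function(n_donors, n_regions, n_probes,
                                 reliability = 0.8, seed = 1L,
                                 geometry = NULL, coord_jitter = 0.02,
                                 weak_fraction = 0.2) {
  if (n_donors < 2) abort("`n_donors` must be >= 2.")
  if (n_regions < 3) abort("`n_regions` must be >= 3.")
  if (reliability < 0 || reliability > 1) abort("`reliability` must be in [0, 1].")
  if (!is.null(geometry) && nrow(geometry) != n_regions) {
    abort("`geometry` must have exactly `n_regions` parcels.")
  }
  probes <- tibble(
    probe = sprintf("probe_%04d", seq_len(n_probes)),
    gene = sprintf("gene_%04d", ceiling(seq_len(n_probes) / 2))
  )
  regions <- if (is.null(geometry)) {
    sprintf("region_%03d", seq_len(n_regions))
  } else {
    geometry$parcel
  }
  shared <- with_seed(split_seed(seed, "shared-profiles"), {
    list(
      profile = matrix(rnorm(n_probes * n_regions), n_probes,
                       dimnames = list(probes$probe, regions)),
      weak = runif(n_probes) < weak_fraction,
      weak_rate = runif(n_probes, 0.5, 0.9),
      strong_rate = runif(n_probes, 0.0, 0.3)
    )
  })
  bg_rate <- ifelse(shared$weak, shared$weak_rate, shared$strong_rate)
  donors <- sprintf("donor_%02d", seq_len(n_donors))
  expr <- background <- samples <- setNames(vector("list", n_donors), donors)
  for (d in seq_len(n_donors)) {
    dseed <- split_seed(seed, paste0("donor-", d))
    res <- with_seed(dseed, {
      noise <- matrix(rnorm(n_probes * n_regions), n_probes)
      e <- reliability * shared$profile + (1 - reliability) * noise
      b <- matrix(runif(n_probes * n_regions) < bg_rate, n_probes)
      jit <- matrix(rnorm(n_regions * 3, 0, coord_jitter), n_regions)
      list(e = e, b = b, jit = jit)
    })
    dimnames(res$e) <- dimnames(res$b) <-
      list(probes$probe, sprintf("%s_s%03d", donors[d], seq_len(n_regions)))
    expr[[d]] <- res$e
    background[[d]] <- res$b
    smp <- tibble(sample = colnames(res$e), region = regions)
    if (!is.null(geometry)) {
      cm <- centroid_matrix(geometry) + res$jit
      cm <- cm / sqrt(rowSums(cm^2))
      smp$x <- cm[, 1]; smp$y <- cm[, 2]; smp$z <- cm[, 3]
    }
    samples[[d]] <- smp
  }
  structure(
    list(probes = probes, regions = regions, expr = expr,
         background = background, samples = samples,
         reliability = reliability, seed = as.integer(seed)),
    class = "donor_expression"
  )
}
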