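test_that("Welch PSD satisfies Parseval and finds spectral lines", {
  # constant signal: no power at positive frequencies
  p0 <- welch_psd(rep(3, 2048), fs = 256)
  expect_lt(max(p0$power[1, -1]), 1e-20)

  set.seed(1)
  x <- rnorm(80 * 256)
  p <- welch_psd(x, fs = 256)
  integral <- sum(p$power[1, ]) * diff(p$freq[1:2])
  expect_equal(integral, var(x), tolerance = 0.05)

  t <- seq(0, 16 - 1 / 256, by = 1 / 256)
  ps <- welch_psd(sin(2 * pi * 10 * t), fs = 256)
  expect_equal(ps$freq[which.max(ps$power[1, ])], 10)

  expect_error(welch_psd(rnorm(100), fs = 256), "Window longer")
})

test_that("band power equals brute-force bin averages and is linear", {
  freq <- seq(0, 100, by = 0.25)
  flat <- psd_from_curve(freq, rep(2.5, length(freq)))
  bp <- band_power(flat)
  expect_true(all(abs(bp$power - 2.5) < 1e-12))

  # support restricted to 8-12 Hz: alpha only
  supp <- ifelse(freq >= 8 & freq <= 12, 1, 0)
  bp2 <- band_power(psd_from_curve(freq, supp))
  expect_gt(bp2$power[bp2$band == "alpha"], 0)
  expect_true(all(bp2$power[!bp2$band %in% c("alpha")] == 0))

  # Lorentzian curve vs an explicit loop oracle
  lor <- 1 / (1 + (freq / 10)^2)
  bp3 <- band_power(psd_from_curve(freq, lor))
  bands <- canonical_bands()
  for (i in seq_len(nrow(bands))) {
    acc <- c()
    for (j in seq_along(freq)) {
      if (freq[j] >= bands$lo[i] && freq[j] <= bands$hi[i]) {
        acc <- c(acc, lor[j])
      }
    }
    expect_equal(bp3$power[bp3$band == bands$band[i]], mean(acc))
  }

  # linearity in the PSD
  p1 <- runif(length(freq)) + 0.1
  p2 <- runif(length(freq)) + 0.1
  lhs <- band_power(psd_from_curve(freq, 3 * p1 + p2))$power
  rhs <- 3 * band_power(psd_from_curve(freq, p1))$power +
    band_power(psd_from_curve(freq, p2))$power
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(
    band_power(flat, tibble::tibble(band = "x", lo = 300, hi = 400)),
    "outside"
  )
})

test_that("spectral model recovers aperiodic parameters and peaks", {
  freq <- seq(0.25, 90, by = 0.25)
  clean <- 10^(0 - log10(100 + freq^2))
  fit <- fit_spectral_model(psd_from_curve(freq, clean))
  expect_lt(abs(fit$aperiodic$knee / 100 - 1), 0.02)
  expect_lt(abs(fit$aperiodic$exponent / 2 - 1), 0.02)
  expect_equal(nrow(fit$peaks), 0)
  expect_gt(fit$aperiodic$r_squared, 0.999)

  peaked <- 10^(0 - log10(100 + freq^2) +
                  0.5 * exp(-(freq - 10)^2 / (2 * 2^2)))
  fit2 <- fit_spectral_model(psd_from_curve(freq, peaked))
  expect_equal(nrow(fit2$peaks), 1)
  expect_lt(abs(fit2$peaks$center - 10), 0.5)

  # 8 injected peaks, cap at 6
  centers <- seq(5, 40, by = 5)
  lp <- 0 - log10(100 + freq^2)
  for (cc in centers) lp <- lp + 0.6 * exp(-(freq - cc)^2 / (2 * 1.5^2))
  fit3 <- fit_spectral_model(psd_from_curve(freq, 10^lp))
  expect_lte(nrow(fit3$peaks), 6)

  expect_error(fit_spectral_model(psd_from_curve(freq, clean), fit_lo = 0),
               "fit_lo")
})

test_that("knee frequency and intrinsic timescale follow their closed forms", {
  kt <- knee_timescale(data.frame(knee = c(100, 1, 8),
                                  exponent = c(2, 3, 3)))
  expect_equal(kt$knee_freq, c(10, 1, 2))
  expect_equal(kt$tau, c(1 / (20 * pi), 1 / (2 * pi), 1 / (4 * pi)))
  expect_true(all(kt$valid))

  bad <- knee_timescale(data.frame(knee = c(-1, 5), exponent = c(2, 0)))
  expect_false(any(bad$valid))
  expect_true(all(is.na(bad$tau)))

  # tau strictly decreasing in f_k; f_k strictly increasing in k at fixed chi
  ks <- seq(1, 200, length.out = 25)
  kt2 <- knee_timescale(data.frame(knee = ks, exponent = 2))
  expect_true(all(diff(kt2$knee_freq) > 0))
  expect_true(all(diff(kt2$tau) < 0))
})

test_that("oscillation scores follow the power-times-probability rule", {
  mk_fit <- function(peaks) {
    structure(list(
      aperiodic = tibble::tibble(parcel = c("A", "B"), offset = 0, knee = 10,
                                 exponent = 2, r_squared = 1,
                                 n_peaks = NA_integer_),
      peaks = peaks, fit_range = c(1, 60), settings = list()
    ), class = "spectral_fit")
  }
  # parcel A: peak powers 2 and 4 across the two participants
  # parcel B: power 8 in participant 1 only
  f1 <- mk_fit(tibble::tibble(parcel = c("A", "B"), center = c(10, 10),
                              height = c(2, 8), width = 1))
  f2 <- mk_fit(tibble::tibble(parcel = "A", center = 10, height = 4,
                              width = 1))
  sc <- suppressWarnings(oscillation_score(list(f1, f2))) # empty other bands
  alpha <- sc[sc$band == "alpha", ]
  expect_equal(alpha$mean_power[alpha$parcel == "A"], 3)
  expect_equal(alpha$mean_power[alpha$parcel == "B"], 8)
  expect_equal(alpha$norm_power, c(0.375, 1))
  expect_equal(alpha$probability, c(1, 0.5))
  expect_equal(alpha$score, c(0.375, 0.5))

  # identical peak everywhere -> score 1 everywhere
  f3 <- mk_fit(tibble::tibble(parcel = c("A", "B"), center = 10,
                              height = 5, width = 1))
  sc3 <- suppressWarnings(oscillation_score(list(f3, f3)))
  expect_equal(sc3$score[sc3$band == "alpha"], c(1, 1))
  # empty band warns and scores zero
  w <- capture_warnings(oscillation_score(list(f3)))
  expect_match(w, "delta", all = FALSE)
  sc_b <- suppressWarnings(oscillation_score(list(f3)))
  expect_true(all(sc_b$score[sc_b$band == "beta"] == 0))
})
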