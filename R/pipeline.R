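#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end synthetic analysis in one list
#' with explicit seeds, so a run is a pure function of its configuration.
#'
#' @param seed Master integer seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param n_per_hemisphere Parcels per hemisphere (default 50, i.e. a
#'   100-parcel atlas).
#' @param n_participants Participants simulated (default 6 for the demo
#'   scale).
#' @param duration_s,fs_hz Recording length and sampling rate (defaults
#'   110 s at 509 Hz: 30 s are dropped before feature extraction and 80 s
#'   retained).
#' @param n_micro_maps Number of micro-architectural maps (default 45).
#' @param micro_coupling,micro_noise_sd Latent coupling and noise of the
#'   micro-architecture generator.
#' @param n_perms Spin permutations (default 1000).
#' @param n_boot Bootstrap resamples (default 500).
#' @param n_splits Distance-dependent CV splits (default 99).
#' @param latent_lengthscale Latent-map smoothness (radians).
#' @param participant_jitter Participant-level spectral jitter.
#' @param stages Character vector of stages to run, a subset of
#'   `c("synthgen", "spectral", "tsfeat", "gradients", "plsmap",
#'   "confounds", "transcriptomic")`.
#' @param out_dir Output directory (`NULL` for no files).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_per_hemisphere = 50,
                            n_participants = 6,
                            duration_s = 110,
                            fs_hz = 509,
                            n_micro_maps = 45,
                            micro_coupling = 0.9,
                            micro_noise_sd = 0.5,
                            n_perms = 1000,
                            n_boot = 500,
                            n_splits = 99,
                            latent_lengthscale = 0.5,
                            participant_jitter = 0,
                            stages = c("synthgen", "spectral", "tsfeat",
                                       "gradients", "plsmap", "confounds",
                                       "transcriptomic"),
                            out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

config_digest <- function(config) {
  flat <- paste(names(config), purrr::map_chr(config, function(v) {
    paste(format(v, digits = 15), collapse = ",")
  }), sep = "=", collapse = ";")
  # "cfg" prefix keeps the digest unambiguously a string in TSV round-trips
  sprintf("cfg%08x", split_seed(0, flat))
}

require_stage <- function(results, stage, needed_by) {
  if (is.null(results[[stage]])) {
    abort(sprintf("Stage '%s' requires '%s', which was not run.",
                  needed_by, stage))
  }
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order and according to `config$stages`: synthetic-data
#' generation (geometry, latent map, graded regional time-series,
#' micro-architecture maps, donor expression), spectral analysis (Welch PSD,
#' band power, knee fits, intrinsic timescale, oscillation scores),
#' time-series feature extraction with normalization and group averaging,
#' the PCA gradient with loadings and map comparisons, PLS with permutation
#' test, bootstrap CIs and distance-dependent CV, SNR/empty-room confound
#' analyses, and expression processing. Deterministic given the
#' configuration; when `config$out_dir` is set, all stage tables are written
#' as TSV together with a JSON run manifest.
#'
#' @param config A `pipeline_config`.
#' @return A named list of stage results (class `pipeline_result`) with the
#'   configuration and manifest attached.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  res <- list()
  t0 <- Sys.time()

  if ("synthgen" %in% stages) {
    geom <- gen_parcellation(config$n_per_hemisphere,
                             seed = split_seed(config$seed, "geometry"))
    latent <- gen_smooth_map(geom, config$latent_lengthscale,
                             seed = split_seed(config$seed, "latent"))
    prof <- graded_profiles(geom, latent)
    ts <- gen_regional_timeseries(
      geom, config$duration_s, config$fs_hz,
      prof$aperiodic, prof$peaks,
      seed = split_seed(config$seed, "timeseries"),
      n_participants = config$n_participants,
      participant_jitter = config$participant_jitter
    )
    micro <- with_seed(split_seed(config$seed, "micro"), {
      w <- rnorm(config$n_micro_maps)
      w <- w / sqrt(sum(w^2))
      config$micro_coupling * tcrossprod(latent, w) +
        config$micro_noise_sd *
          matrix(rnorm(nrow(geom) * config$n_micro_maps), nrow(geom))
    })
    dimnames(micro) <- list(geom$parcel,
                            sprintf("micro_%02d", seq_len(config$n_micro_maps)))
    res$synthgen <- list(geometry = geom, latent = latent, profiles = prof,
                         timeseries = ts, micro = micro)
  }

  ens <- NULL
  if (any(c("gradients", "plsmap", "confounds") %in% stages)) {
    require_stage(res, "synthgen", "spin ensemble")
    ens <- make_spin_ensemble(res$synthgen$geometry, config$n_perms,
                              seed = split_seed(config$seed, "spins"))
  }

  if ("spectral" %in% stages) {
    require_stage(res, "synthgen", "spectral")
    ts <- res$synthgen$timeseries
    fits <- purrr::map(seq_along(ts$data), function(p) {
      fit_spectral_model(welch_psd(ts, participant = p))
    })
    psd1 <- welch_psd(ts, participant = 1)
    bp <- purrr::map_dfr(seq_along(ts$data), function(p) {
      band_power(welch_psd(ts, participant = p)) %>%
        mutate(participant = p)
    }) %>%
      group_by(.data$parcel, .data$band) %>%
      summarise(power = mean(.data$power), .groups = "drop")
    taus <- purrr::map_dfr(seq_along(fits), function(p) {
      knee_timescale(fits[[p]]) %>% mutate(participant = p)
    }) %>%
      group_by(.data$parcel) %>%
      summarise(tau = mean(.data$tau[.data$valid]), .groups = "drop")
    res$spectral <- list(fits = fits, psd = psd1, band_power = bp,
                         timescale = taus,
                         oscillation = oscillation_score(fits))
  }

  if ("tsfeat" %in% stages) {
    require_stage(res, "synthgen", "tsfeat")
    fms <- compute_feature_matrices(res$synthgen$timeseries)
    fms_norm <- purrr::map(fms, normalize_feature_matrix)
    res$tsfeat <- list(per_participant = fms_norm,
                       group = aggregate_group(fms_norm))
  }

  if ("gradients" %in% stages) {
    require_stage(res, "tsfeat", "gradients")
    pca <- fit_pca(res$tsfeat$group)
    loadings <- component_loadings(res$tsfeat$group, pca, ens)
    comparisons <- NULL
    if (!is.null(res$spectral)) {
      bp_wide <- tidyr::pivot_wider(res$spectral$band_power,
                                    names_from = "band",
                                    values_from = "power")
      bp_wide <- bp_wide[match(pca$parcel, bp_wide$parcel), ]
      fam <- as.matrix(bp_wide[, -1])
      tau <- res$spectral$timescale
      fam <- cbind(fam, timescale = tau$tau[match(pca$parcel, tau$parcel)])
      keep <- complete.cases(t(fam))
      comparisons <- correlate_maps(fam[, keep, drop = FALSE],
                                    pca$scores[, 1], ens)
    }
    res$gradients <- list(pca = pca, loadings = loadings,
                          comparisons = comparisons,
                          latent_alignment = cor(
                            pca$scores[, 1], res$synthgen$latent,
                            method = "spearman"
                          ))
  }

  if ("plsmap" %in% stages) {
    require_stage(res, "tsfeat", "plsmap")
    x <- res$tsfeat$group$values
    y <- res$synthgen$micro
    fit <- pls_fit(x, y)
    perm <- pls_permutation_test(x, y, ens)
    boot <- pls_bootstrap_loadings(x, y, n_boot = config$n_boot,
                                   seed = split_seed(config$seed, "boot"))
    cv <- distance_dependent_cv(x, y, res$synthgen$geometry,
                                n_splits = min(config$n_splits, nrow(x)),
                                seed = split_seed(config$seed, "cv"))
    res$plsmap <- list(fit = fit, permutation = perm, bootstrap = boot,
                       cv = cv)
  }

  if ("confounds" %in% stages) {
    require_stage(res, "tsfeat", "confounds")
    geom <- res$synthgen$geometry
    snr_map <- gen_smooth_map(geom, config$latent_lengthscale,
                              seed = split_seed(config$seed, "snr"))
    filt <- snr_feature_filter(res$tsfeat$group, snr_map, ens)
    resid <- regress_covariate(res$tsfeat$group, snr_map)
    # empty-room-like recordings: spatially uniform spectra, fewer sessions
    flat <- tibble(parcel = geom$parcel, offset = 0, knee = 30, exponent = 1.5)
    noise_ts <- gen_regional_timeseries(
      geom, config$duration_s, config$fs_hz, flat, NULL,
      seed = split_seed(config$seed, "emptyroom"),
      n_participants = min(2, config$n_participants)
    )
    noise_fm <- aggregate_group(
      purrr::map(compute_feature_matrices(noise_ts), normalize_feature_matrix)
    )
    res$confounds <- list(
      snr_map = snr_map, filter = filt, residual = resid,
      noise_comparison = noise_component_comparison(res$tsfeat$group,
                                                    noise_fm, ens)
    )
  }

  if ("transcriptomic" %in% stages) {
    require_stage(res, "synthgen", "transcriptomic")
    geom <- res$synthgen$geometry
    dex <- gen_donor_expression(
      n_donors = 6, n_regions = nrow(geom), n_probes = 300,
      reliability = 0.8, seed = split_seed(config$seed, "expression"),
      geometry = geom
    )
    rem <- regional_expression_matrix(dex, geom)
    classes <- c("astro", "endo", "micro", "neuron_ex", "neuron_in",
                 "oligo", "opc")
    genes <- colnames(rem$expression)
    gene_sets <- with_seed(split_seed(config$seed, "genesets"), {
      shuffled <- sample(genes)
      split(shuffled[seq_len(7 * min(10, length(genes) %/% 7))],
            rep(classes, each = min(10, length(genes) %/% 7)))
    })
    res$transcriptomic <- list(expression = rem,
                               cell_maps = celltype_expression_maps(
                                 rem$expression, gene_sets
                               ))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dynmap")),
    config_digest = config_digest(config),
    seed = config$seed,
    stages = stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    if (!is.null(res$synthgen)) {
      write_geometry(res$synthgen$geometry, file.path(od, "geometry.tsv"))
      write_maps(tibble(parcel = res$synthgen$geometry$parcel,
                        latent = res$synthgen$latent,
                        digest = manifest$config_digest),
                 file.path(od, "latent_map.tsv"))
    }
    if (!is.null(res$spectral)) {
      readr::write_tsv(res$spectral$band_power %>%
                         mutate(digest = manifest$config_digest),
                       file.path(od, "band_power.tsv"))
      readr::write_tsv(res$spectral$timescale %>%
                         mutate(digest = manifest$config_digest),
                       file.path(od, "timescale.tsv"))
    }
    if (!is.null(res$tsfeat)) {
      write_feature_matrix(res$tsfeat$group,
                           file.path(od, "group_features.tsv"))
    }
    if (!is.null(res$gradients)) {
      readr::write_tsv(augment(res$gradients$pca) %>%
                         mutate(digest = manifest$config_digest),
                       file.path(od, "pc_scores.tsv"))
      readr::write_tsv(res$gradients$loadings %>%
                         mutate(digest = manifest$config_digest),
                       file.path(od, "pc1_loadings.tsv"))
    }
    if (!is.null(res$plsmap)) {
      readr::write_tsv(res$plsmap$permutation %>%
                         mutate(digest = manifest$config_digest),
                       file.path(od, "pls_permutation.tsv"))
      readr::write_tsv(res$plsmap$bootstrap %>%
                         mutate(digest = manifest$config_digest),
                       file.path(od, "pls_bootstrap.tsv"))
      readr::write_tsv(res$plsmap$cv %>%
                         mutate(digest = manifest$config_digest),
                       file.path(od, "pls_cv.tsv"))
    }
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(c(res, list(config = config, manifest = manifest)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> stages: %s | seed %d | %.1f s\n",
              paste(setdiff(names(x), c("config", "manifest")),
                    collapse = ", "),
              x$config$seed, x$manifest$elapsed_s))
  invisible(x)
}
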