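#' Filter probes by expression intensity relative to background
#'
#' A probe is discarded when its intensity falls below background in at
#' least `threshold` (default 50%) of samples pooled across donors.
#'
#' @param dex A `donor_expression` object.
#' @param threshold Below-background fraction at or above which a probe is
#'   discarded (default 0.5).
#' @return Tibble with `probe`, `gene`, `below_background_frac`, `retained`.
#' @export
probe_intensity_filter <- function(dex, threshold = 0.5) {
  stopifnot(inherits(dex, "donor_expression"))
  below <- do.call(cbind, dex$background)
  n_samples <- ncol(below)
  if (n_samples == 0) abort("No samples present.")
  frac <- rowMeans(below)
  tibble(probe = dex$probes$probe, gene = dex$probes$gene,
         below_background_frac = frac,
         retained = frac < threshold)
}

#' Differential stability and per-gene probe selection
#'
#' The differential stability of a probe is the mean, over all donor pairs,
#' of the Spearman correlation between its regional expression profiles in
#' the two donors: `DS(p) = (1 / C(N,2)) * sum_{i<j} rho(B_i(p), B_j(p))`.
#' When several probes index one gene, the probe with maximal DS is selected.
#'
#' @param dex A `donor_expression` object.
#' @param probes Optional character vector restricting the candidate probes
#'   (e.g. the `retained` set from [probe_intensity_filter()]).
#' @param parcel_assignment Optional named list/vector mapping each sample to
#'   a region; by default samples are used with the regions recorded in the
#'   generator (one sample per region).
#' @return List with `ds` (tibble `probe`, `gene`, `ds`) and `selected`
#'   (tibble `gene`, `probe`, `ds`; genes with no surviving probes are
#'   dropped with a warning).
#' @export
differential_stability_select <- function(dex, probes = NULL,
                                          parcel_assignment = NULL) {
  stopifnot(inherits(dex, "donor_expression"))
  if (length(dex$expr) < 2) abort("Need at least 2 donors.")
  cand <- if (is.null(probes)) dex$probes$probe else probes
  # per-donor probe x region profile (mean over samples in a region)
  profiles <- purrr::imap(dex$expr, function(e, d) {
    reg <- if (is.null(parcel_assignment)) {
      dex$samples[[d]]$region
    } else {
      parcel_assignment[[d]]
    }
    t(apply(e[cand, , drop = FALSE], 1, function(row) {
      tapply(row, reg, mean)
    }))
  })
  regions <- Reduce(intersect, purrr::map(profiles, colnames))
  if (length(regions) < 3) abort("Need >= 3 common regions per donor pair.")
  nd <- length(profiles)
  pairs <- utils::combn(nd, 2)
  ds_vals <- rowMeans(matrix(vapply(seq_len(ncol(pairs)), function(k) {
    a <- profiles[[pairs[1, k]]][, regions, drop = FALSE]
    b <- profiles[[pairs[2, k]]][, regions, drop = FALSE]
    vapply(seq_len(nrow(a)), function(i) {
      suppressWarnings(cor(a[i, ], b[i, ], method = "spearman"))
    }, numeric(1))
  }, numeric(length(cand))), nrow = length(cand)))
  ds <- tibble(probe = cand,
               gene = dex$probes$gene[match(cand, dex$probes$probe)],
               ds = ds_vals)
  dropped <- setdiff(unique(dex$probes$gene), unique(ds$gene))
  if (length(dropped) > 0) {
    warn(sprintf("%d gene(s) have no surviving probes and were dropped.",
                 length(dropped)))
  }
  selected <- ds %>%
    filter(is.finite(.data$ds)) %>%
    group_by(.data$gene) %>%
    arrange(dplyr::desc(.data$ds), .data$probe, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select("gene", "probe", "ds")
  list(ds = ds, selected = selected)
}

#' Robust sigmoid normalization to the unit interval
#'
#' `x_norm = 1 / (1 + exp(-(x - median(x)) / IQR(x)))` followed by
#' `x_scaled = (x_norm - min) / (max - min)`. The IQR is used bare here (the
#' expression-processing convention); entries of a vector with zero IQR are
#' flagged invalid (`NA`).
#'
#' @param x Numeric vector (>= 3 finite entries).
#' @return Numeric vector in `[0, 1]` (or `NA`s when IQR is zero).
#' @export
robust_sigmoid_rescale <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 3) abort("Need >= 3 finite entries.")
  iqr <- stats::IQR(x[ok])
  if (iqr == 0) return(rep(NA_real_, length(x)))
  xn <- 1 / (1 + exp(-(x - median(x[ok])) / iqr))
  rng <- range(xn[ok])
  out <- (xn - rng[1]) / diff(rng)
  out[!ok] <- NA_real_
  out
}

#' Two-stage normalization of an expression table
#'
#' Applies the robust sigmoid + unit rescale first across genes within each
#' tissue sample, then across samples within each gene — addressing
#' inter-subject variation before cross-sample comparison. The two stages do
#' not commute; the order here is the documented convention.
#'
#' @param m Numeric matrix, genes (or probes) x samples.
#' @return Matrix of the same shape with values in `[0, 1]` (NA where a
#'   stage had zero IQR).
#' @export
normalize_expression <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3 || ncol(m) < 3) {
    abort("Need >= 3 entries per normalization axis.")
  }
  m <- apply(m, 2, robust_sigmoid_rescale)            # across genes, per sample
  t(apply(m, 1, robust_sigmoid_rescale))              # across samples, per gene
}

#' Assign tissue samples to parcels, with mirroring and distance fill
#'
#' Each sample (and, when `mirror = TRUE`, its x-mirrored copy) is assigned
#' to the nearest parcel centroid within `max_dist`; samples beyond
#' `max_dist` of every centroid are excluded. Parcels left without samples
#' are filled by an inverse-distance-weighted average over all assigned
#' samples — the centroid-level analogue of dense volumetric interpolation,
#' preserving the statistical role (no empty parcels).
#'
#' @param samples Tibble with columns `sample`, `x`, `y`, `z` (unit-sphere
#'   coordinates).
#' @param geometry A `parcellation` tibble.
#' @param max_dist Assignment radius in radians of great-circle distance
#'   (the synthetic analogue of a 2 mm rule; default 0.1).
#' @param mirror Mirror samples across hemispheres (default TRUE).
#' @return Tibble with `sample`, `mirrored`, `parcel`, `distance`
#'   (unassigned samples are absent); attribute `"unassigned"` lists
#'   excluded sample ids.
#' @export
assign_samples_to_parcels <- function(samples, geometry, max_dist = 0.1,
                                      mirror = TRUE) {
  sm <- as.matrix(samples[, c("x", "y", "z")])
  sm <- sm / sqrt(rowSums(sm^2))
  ids <- samples$sample
  if (mirror) {
    smm <- sm
    smm[, 1] <- -smm[, 1]
    sm <- rbind(sm, smm)
    mirrored <- rep(c(FALSE, TRUE), each = length(ids))
    ids <- c(ids, ids)
  } else {
    mirrored <- rep(FALSE, length(ids))
  }
  cm <- centroid_matrix(geometry)
  d <- angular_distance(sm, cm)
  nearest <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(d)), nearest)]
  ok <- dist <= max_dist
  out <- tibble(sample = ids[ok], mirrored = mirrored[ok],
                parcel = geometry$parcel[nearest[ok]], distance = dist[ok])
  attr(out, "unassigned") <- unique(ids[!ok])
  out
}

#' Build the regional expression matrix from donor data
#'
#' Full expression-processing pathway: probe intensity filtering,
#' differential-stability probe selection, two-stage robust-sigmoid
#' normalization of each donor's probe x sample table, sample-to-parcel
#' assignment with mirroring, donor-wise averaging within parcels and then
#' averaging across donors; parcels with no assigned samples are filled by
#' inverse-distance-weighted averages over assigned samples.
#'
#' @param dex A `donor_expression` object with sample coordinates (generate
#'   with a `geometry`).
#' @param geometry A `parcellation` tibble.
#' @param intensity_threshold Passed to [probe_intensity_filter()].
#' @param max_dist,mirror Passed to [assign_samples_to_parcels()].
#' @return List with `expression` (parcels x genes matrix in `[0, 1]`),
#'   `probes` (per-gene selected probe + DS), `filter_report`.
#' @export
regional_expression_matrix <- function(dex, geometry,
                                       intensity_threshold = 0.5,
                                       max_dist = 0.1, mirror = TRUE) {
  stopifnot(inherits(dex, "donor_expression"))
  if (!all(c("x", "y", "z") %in% names(dex$samples[[1]]))) {
    abort("Donor samples carry no coordinates; regenerate with a geometry.")
  }
  filt <- probe_intensity_filter(dex, intensity_threshold)
  kept <- filt$probe[filt$retained]
  if (length(kept) == 0) abort("All probes failed the intensity filter.")
  sel <- differential_stability_select(dex, probes = kept)
  probes <- sel$selected$probe
  genes <- sel$selected$gene
  per_donor <- purrr::imap(dex$expr, function(e, d) {
    norm <- normalize_expression(e[probes, , drop = FALSE])
    asg <- assign_samples_to_parcels(dex$samples[[d]], geometry,
                                     max_dist = max_dist, mirror = mirror)
    filled <- matrix(NA_real_, nrow(geometry), length(probes),
                     dimnames = list(geometry$parcel, probes))
    for (p in unique(asg$parcel)) {
      cols <- asg$sample[asg$parcel == p]
      filled[p, ] <- rowMeans(norm[, cols, drop = FALSE])
    }
    empty <- rownames(filled)[!complete.cases(filled)]
    if (length(empty) > 0) {
      # inverse-distance-weighted fill over this donor's assigned samples
      scoords <- as.matrix(dex$samples[[d]][, c("x", "y", "z")])
      scoords <- scoords / sqrt(rowSums(scoords^2))
      rownames(scoords) <- dex$samples[[d]]$sample
      used <- unique(asg$sample[!asg$mirrored])
      cm <- centroid_matrix(geometry)
      for (p in empty) {
        dd <- angular_distance(cm[p, , drop = FALSE],
                               scoords[used, , drop = FALSE])[1, ]
        w <- 1 / pmax(dd, 1e-6)
        filled[p, ] <- as.vector(norm[, used, drop = FALSE] %*% (w / sum(w)))
      }
    }
    filled
  })
  expr <- Reduce(`+`, per_donor) / length(per_donor)
  colnames(expr) <- genes
  list(expression = expr, probes = sel$selected, filter_report = filt)
}

#' Cell-class mean expression maps
#'
#' Per cell class, the unweighted mean over the class's gene columns of a
#' regional expression matrix.
#'
#' @param expr Parcels x genes numeric matrix (gene column names).
#' @param gene_sets Named list of character vectors of gene names (e.g. the
#'   seven canonical classes: astro, endo, micro, neuron_ex, neuron_in,
#'   oligo, opc).
#' @return Tibble with `parcel`, `cell_class`, `expression`; genes missing
#'   from the matrix are dropped with a warning, a class with no matched
#'   genes is an error.
#' @export
celltype_expression_maps <- function(expr, gene_sets) {
  expr <- as.matrix(expr)
  purrr::imap_dfr(gene_sets, function(genes, cls) {
    present <- intersect(genes, colnames(expr))
    if (length(present) == 0) {
      abort(sprintf("Cell class '%s' matched no genes.", cls))
    }
    if (length(present) < length(genes)) {
      warn(sprintf("Cell class '%s': %d gene(s) missing from the matrix.",
                   cls, length(genes) - length(present)))
    }
    tibble(parcel = rownames(expr), cell_class = cls,
           expression = unname(rowMeans(expr[, present, drop = FALSE])))
  })
}
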