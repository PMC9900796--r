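# uniform random rotation matrices via normalized quaternions
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Build a spin-permutation ensemble on a parcellation
#'
#' Spatial-autocorrelation-preserving permutations: for each repetition a
#' uniform random 3D rotation is applied to the left-hemisphere centroids and
#' its x-mirrored conjugate to the right hemisphere; each rotated centroid is
#' then reassigned the index of the nearest original centroid of the same
#' hemisphere (great-circle distance). Because nearest-reassignment is not a
#' bijection, indices within a row may repeat.
#'
#' @param geometry A `parcellation` tibble with both hemispheres.
#' @param n_perms Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param include_identity If `TRUE`, row 1 is the identity permutation.
#' @return An object of class `spin_ensemble`: integer matrix `perms`
#'   (`n_perms` x parcels; entry `[r, i]` is the parcel whose value parcel
#'   `i` receives in permutation `r`), plus `seed` and a geometry
#'   fingerprint.
#' @export
make_spin_ensemble <- function(geometry, n_perms = 1000, seed = 1L,
                               include_identity = FALSE) {
  if (length(unique(geometry$hemi)) < 2) {
    abort("Geometry must contain both hemispheres.")
  }
  cm <- centroid_matrix(geometry)
  left <- which(geometry$hemi == "L")
  right <- which(geometry$hemi == "R")
  mirror <- diag(c(-1, 1, 1))
  perms <- matrix(NA_integer_, n_perms, nrow(geometry))
  with_seed(split_seed(seed, "spins"), {
    for (r in seq_len(n_perms)) {
      if (include_identity && r == 1L) {
        perms[r, ] <- seq_len(nrow(geometry))
        next
      }
      rot <- random_rotation()
      rot_r <- mirror %*% rot %*% mirror # conjugate by x-reflection
      for (side in list(list(idx = left, m = rot),
                        list(idx = right, m = rot_r))) {
        rotated <- cm[side$idx, , drop = FALSE] %*% t(side$m)
        # nearest original same-hemisphere centroid = max cosine similarity
        sim <- tcrossprod(rotated, cm[side$idx, , drop = FALSE])
        perms[r, side$idx] <- side$idx[max.col(sim, ties.method = "first")]
      }
    }
  })
  structure(
    list(perms = perms, seed = as.integer(seed),
         n_perms = as.integer(n_perms),
         geometry_fingerprint = paste0(
           nrow(geometry), ":",
           format(sum(cm * seq_len(length(cm))), digits = 15)
         ),
         hemi = geometry$hemi),
    class = "spin_ensemble"
  )
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble> %d permutations x %d parcels (seed %d)\n",
              nrow(x$perms), ncol(x$perms), x$seed))
  invisible(x)
}

# ranks of each row of a matrix (average ties), used to vectorize Spearman
row_ranks <- function(m) t(apply(m, 1, rank))

# correlations between each permuted copy of `a` and fixed `b`
null_correlations <- function(a, b, ensemble, statistic) {
  perm_a <- matrix(a[t(ensemble$perms)], nrow = nrow(ensemble$perms),
                   byrow = TRUE)
  if (statistic == "spearman") {
    perm_a <- row_ranks(perm_a)
    b <- rank(b)
  }
  as.vector(cor(t(perm_a), b))
}

#' Spin-test p-value for the association of two brain maps
#'
#' The observed statistic is compared with its distribution over spun copies
#' of `map_a` (permuted by the ensemble rows) against the fixed `map_b`. The
#' two-sided p-value uses the plus-one convention
#' `p = (1 + #(|null| >= |obs|)) / (1 + n_perms)` and can therefore never be
#' zero.
#'
#' @param map_a,map_b Numeric vectors aligned to the ensemble's parcellation.
#' @param ensemble A `spin_ensemble`.
#' @param statistic `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble with `statistic`, `estimate`, `p_spin`, `n_perms`.
#' @export
spin_pvalue <- function(map_a, map_b, ensemble,
                        statistic = c("spearman", "pearson")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(ensemble, "spin_ensemble"))
  if (length(map_a) != ncol(ensemble$perms) ||
      length(map_b) != ncol(ensemble$perms)) {
    abort("Maps must match the ensemble's parcel count.")
  }
  if (sd(map_a) == 0 || sd(map_b) == 0) {
    abort("Constant map: correlation undefined.")
  }
  obs <- cor(map_a, map_b, method = statistic)
  nulls <- null_correlations(map_a, map_b, ensemble, statistic)
  p <- (1 + sum(abs(nulls) >= abs(obs))) / (1 + length(nulls))
  tibble(statistic = statistic, estimate = obs, p_spin = p,
         n_perms = length(nulls))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment with a rejection mask at level `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Tibble with `p`, `p_fdr` (monotone adjusted values) and
#'   `significant`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) abort("Empty p-value vector.")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble(p = p_values, p_fdr = adj, significant = !is.na(adj) & adj <= q)
}
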