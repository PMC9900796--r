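# Tab-separated readers/writers with schema validation. All tabular outputs
# are plain TSV so runs are diffable and portable.

#' Write / read a parcellation geometry as TSV
#'
#' @param geometry A `parcellation` tibble.
#' @param path Output file.
#' @return `write_geometry` returns `path` invisibly; `read_geometry`
#'   returns a validated `parcellation` tibble (non-unit centroids are a
#'   schema error naming the offending row).
#' @export
write_geometry <- function(geometry, path) {
  readr::write_tsv(as_tibble(geometry[, c("parcel", "hemi", "x", "y", "z")]),
                   path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         parcel = readr::col_character(),
                         hemi = readr::col_character(),
                         .default = readr::col_double()
                       ))
  if (!all(c("parcel", "hemi", "x", "y", "z") %in% names(g))) {
    abort("Geometry file must have columns parcel, hemi, x, y, z.")
  }
  if (anyDuplicated(g$parcel)) abort("Duplicated parcel ids in geometry file.")
  norms <- sqrt(g$x^2 + g$y^2 + g$z^2)
  bad <- which(abs(norms - 1) > 1e-6)
  if (length(bad) > 0) {
    abort(sprintf("Non-unit centroid in row %d (parcel %s).",
                  bad[1], g$parcel[bad[1]]))
  }
  class(g) <- c("parcellation", class(g))
  g
}

#' Write / read a feature matrix as a TSV pair
#'
#' Values and the validity mask are stored side by side
#' (`<path>` and `<path>.mask.tsv`), with the catalog embedded as a header
#' comment-free companion (`<path>.catalog.tsv`).
#'
#' @param fm A `feature_matrix`.
#' @param path Output file for the values table.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` reconstructs the `feature_matrix` (duplicate
#'   feature names are a schema error).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- as_tibble(fm$values)
  vals <- bind_cols(tibble(parcel = rownames(fm$values)), vals)
  readr::write_tsv(vals, path)
  msk <- as_tibble(fm$valid)
  msk <- bind_cols(tibble(parcel = rownames(fm$valid)), msk)
  readr::write_tsv(msk, paste0(path, ".mask.tsv"))
  readr::write_tsv(
    fm$catalog %>% mutate(state = fm$state, participant = fm$participant),
    paste0(path, ".catalog.tsv")
  )
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  vals <- suppressMessages(
    readr::read_tsv(path, show_col_types = FALSE, name_repair = "minimal")
  )
  if (anyDuplicated(names(vals))) {
    abort("Duplicated feature name in feature-matrix file.")
  }
  msk <- readr::read_tsv(paste0(path, ".mask.tsv"), show_col_types = FALSE)
  cat_tbl <- readr::read_tsv(paste0(path, ".catalog.tsv"),
                             show_col_types = FALSE)
  vm <- as.matrix(vals[, -1])
  rownames(vm) <- vals$parcel
  mm <- as.matrix(msk[, -1])
  rownames(mm) <- msk$parcel
  feature_matrix(vm, cat_tbl %>% select("feature", "family"),
                 valid = mm, state = cat_tbl$state[1],
                 participant = cat_tbl$participant[1])
}

#' Write a per-parcel map table as TSV
#'
#' @param maps Tibble (or named list of vectors) of per-parcel values; must
#'   contain a `parcel` column when a tibble.
#' @param path Output file.
#' @export
write_maps <- function(maps, path) {
  if (!is.data.frame(maps)) {
    maps <- bind_cols(tibble(parcel = names(maps[[1]])), as_tibble(maps))
  }
  readr::write_tsv(maps, path)
  invisible(path)
}

#' Persist a spin ensemble as a compact integer TSV
#'
#' @param ensemble A `spin_ensemble`.
#' @param path Output file.
#' @export
write_spin_ensemble <- function(ensemble, path) {
  readr::write_tsv(as_tibble(ensemble$perms, .name_repair = "minimal"),
                   path, col_names = FALSE)
  meta <- tibble(seed = ensemble$seed, n_perms = ensemble$n_perms,
                 geometry_fingerprint = ensemble$geometry_fingerprint)
  readr::write_tsv(meta, paste0(path, ".meta.tsv"))
  invisible(path)
}
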