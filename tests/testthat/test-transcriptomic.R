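test_that("probe intensity filter applies the >= 50% discard rule", {
  dex <- gen_donor_expression(2, 10, 3, reliability = 1, seed = 30)
  # craft background flags: probe 1 never below, probe 2 below in 49% of
  # samples (pooled), probe 3 below in exactly 50%
  n_s <- 10
  flags <- function(k_below_total) {
    f1 <- matrix(FALSE, 3, n_s)
    f2 <- matrix(FALSE, 3, n_s)
    pooled <- c(rep(TRUE, k_below_total), rep(FALSE, 2 * n_s - k_below_total))
    f1[3, ] <- pooled[1:n_s]
    f2[3, ] <- pooled[(n_s + 1):(2 * n_s)]
    list(f1, f2)
  }
  # 49%-ish case: 9 of 20 below background
  dex$background <- setNames(flags(9), names(dex$background))
  dex$background[[1]][2, ] <- c(rep(TRUE, 5), rep(FALSE, 5))
  dex$background[[2]][2, ] <- c(rep(TRUE, 4), rep(FALSE, 6))
  res <- probe_intensity_filter(dex)
  expect_true(res$retained[1])
  expect_true(res$retained[2])  # 9/20 = 45% below
  expect_true(res$retained[3])  # 9/20 below
  # exactly 50%: discarded
  dex$background <- setNames(flags(10), names(dex$background))
  res2 <- probe_intensity_filter(dex)
  expect_false(res2$retained[3])
  # 55%: discarded
  dex$background <- setNames(flags(11), names(dex$background))
  expect_false(probe_intensity_filter(dex)$retained[3])
})

test_that("differential stability equals the mean pairwise Spearman rho", {
  mk_dex <- function(profiles) {
    # profiles: list of donor matrices probe x region
    np <- nrow(profiles[[1]]); nr <- ncol(profiles[[1]])
    probes <- tibble::tibble(probe = sprintf("p%02d", 1:np),
                             gene = sprintf("g%02d", 1:np))
    regions <- sprintf("region_%03d", 1:nr)
    donors <- sprintf("donor_%02d", seq_along(profiles))
    expr <- purrr::map(profiles, function(m) {
      dimnames(m) <- list(probes$probe, paste0("s", 1:nr))
      m
    })
    names(expr) <- donors
    samples <- purrr::map(donors, function(d) {
      tibble::tibble(sample = paste0("s", 1:nr), region = regions)
    })
    names(samples) <- donors
    structure(list(probes = probes, regions = regions, expr = expr,
                   background = NULL, samples = samples,
                   reliability = NA, seed = 0L),
              class = "donor_expression")
  }
  base <- matrix(c(1, 2, 3, 4, 5), 1)
  # identical profiles -> DS = 1; reversed -> DS = -1
  expect_equal(differential_stability_select(mk_dex(list(base, base)))$ds$ds, 1)
  expect_equal(
    differential_stability_select(mk_dex(list(base, base[, 5:1, drop = FALSE])))$ds$ds,
    -1
  )
  # three donors with pairwise rho (1, 0.5, 0.5) -> DS = 2/3
  p1 <- matrix(c(1, 2, 3, 4, 5), 1)
  p2 <- p1
  p3 <- matrix(c(1, 4, 2, 5, 3), 1) # rank displacement sum 10 -> rho 0.5
  rho13 <- cor(p1[1, ], p3[1, ], method = "spearman")
  ds3 <- differential_stability_select(mk_dex(list(p1, p2, p3)))$ds$ds
  expect_equal(ds3, (1 + rho13 + rho13) / 3)
  expect_equal(ds3, 2 / 3) # rho13 = 0.5 by construction

  # per-gene selection takes the most stable probe
  two_probe <- mk_dex(list(rbind(p1, p3), rbind(p1, p1)))
  two_probe$probes$gene <- c("g1", "g1")
  sel <- differential_stability_select(two_probe)
  expect_equal(nrow(sel$selected), 1)
  expect_equal(sel$selected$probe, "p01")
})

test_that("DS is invariant to monotone transforms and tracks reliability", {
  dexes <- purrr::map(c(0.1, 0.4, 0.7, 0.9), function(r) {
    gen_donor_expression(4, 20, 60, reliability = r, seed = 33)
  })
  mean_ds <- purrr::map_dbl(dexes, function(d) {
    mean(differential_stability_select(d)$ds$ds)
  })
  expect_true(all(diff(mean_ds) > 0))

  d <- dexes[[4]]
  ds_raw <- differential_stability_select(d)$ds$ds
  d_exp <- d
  d_exp$expr <- purrr::map(d$expr, exp) # monotone transform
  expect_equal(differential_stability_select(d_exp)$ds$ds, ds_raw)
  expect_true(all(ds_raw >= -1 & ds_raw <= 1))
})

test_that("two-stage robust sigmoid normalization matches the formula", {
  v <- c(0, 1, 2, 10)
  expect_equal(robust_sigmoid_rescale(v), sigmoid_rescale_oracle(v))
  # median maps to sigmoid midpoint before rescale
  x <- c(1, 5, 9)
  iqr <- stats::IQR(x)
  xn <- 1 / (1 + exp(-(x - 5) / iqr))
  expect_equal(xn[2], 0.5)
  expect_equal(range(robust_sigmoid_rescale(v)), c(0, 1))
  expect_true(all(is.na(robust_sigmoid_rescale(c(2, 2, 2, 2)))))

  m <- matrix(rnorm(30), 5)
  norm <- normalize_expression(m)
  expect_true(all(norm >= 0 & norm <= 1, na.rm = TRUE))
  # order dependence: gene-then-sample differs from sample-then-gene
  alt <- apply(t(apply(m, 1, robust_sigmoid_rescale)), 2,
               robust_sigmoid_rescale)
  expect_false(isTRUE(all.equal(norm, alt)))
})

test_that("sample assignment respects distance, mirroring and fill", {
  geom <- toy_geometry()
  # a sample exactly at a centroid goes to that parcel
  s1 <- tibble::tibble(sample = "s1", x = geom$x[3], y = geom$y[3],
                       z = geom$z[3])
  asg <- assign_samples_to_parcels(s1, geom, mirror = FALSE)
  expect_equal(asg$parcel, geom$parcel[3])
  expect_equal(asg$distance, 0, tolerance = 1e-9)

  # mirroring adds the x-reflected assignment in the other hemisphere
  asg_m <- assign_samples_to_parcels(s1, geom, mirror = TRUE)
  expect_equal(nrow(asg_m), 2)
  hemis <- geom$hemi[match(asg_m$parcel, geom$parcel)]
  expect_setequal(hemis, c("L", "R"))
  mirrored_row <- asg_m[asg_m$mirrored, ]
  target <- geom[match(mirrored_row$parcel, geom$parcel), ]
  expect_equal(target$x, -geom$x[3], tolerance = 1e-9)

  # far samples excluded
  far <- tibble::tibble(sample = "far", x = 0, y = 0, z = 1)
  d_min <- min(acos(pmin(pmax(
    as.matrix(geom[, c("x", "y", "z")]) %*% c(0, 0, 1), -1), 1)))
  asg_far <- assign_samples_to_parcels(far, geom, max_dist = d_min / 2,
                                       mirror = FALSE)
  expect_equal(nrow(asg_far), 0)
  expect_equal(attr(asg_far, "unassigned"), "far")
})

test_that("regional expression pipeline yields unit-interval gene maps", {
  geom <- toy_geometry()
  dex <- gen_donor_expression(3, nrow(geom), 60, reliability = 0.9,
                              seed = 35, geometry = geom)
  rem <- suppressWarnings(regional_expression_matrix(dex, geom))
  expect_equal(nrow(rem$expression), nrow(geom))
  expect_true(all(rem$expression >= 0 & rem$expression <= 1, na.rm = TRUE))
  expect_true(all(complete.cases(rem$expression)))
  expect_false(anyDuplicated(colnames(rem$expression)) > 0)

  maps <- celltype_expression_maps(
    rem$expression,
    list(cls_a = colnames(rem$expression)[1],
         cls_b = colnames(rem$expression)[2:4])
  )
  expect_equal(maps$expression[maps$cell_class == "cls_a"],
               unname(rem$expression[, 1]))
  # brute-force mean oracle for the 3-gene set
  acc <- rep(0, nrow(geom))
  for (g in colnames(rem$expression)[2:4]) acc <- acc + rem$expression[, g]
  expect_equal(maps$expression[maps$cell_class == "cls_b"],
               unname(acc / 3))
  expect_error(celltype_expression_maps(rem$expression, list(bad = "nope")),
               "matched no genes")
})
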