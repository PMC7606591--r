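null_fit <- function(mesh, n = 40, fwhm = 10, seed = 81) {
  set.seed(seed)
  Y <- matrix(rnorm(n * mesh$V), n, mesh$V)
  if (fwhm > 0) Y <- smooth_field(mesh, Y, fwhm)
  fit_ols(Y, cbind(intercept = 1, x = rnorm(n)))
}

test_that("smoothness estimator recovers the generating FWHM", {
  m <- make_icosphere(4)
  fit10 <- null_fit(m, fwhm = 10)
  sm10 <- estimate_smoothness(fit10, m)
  expect_lt(abs(sm10$fwhm_median - 10), 2)
  # unsmoothed residuals: roughness at the mesh-edge scale, clearly
  # below the smoothed case
  fit0 <- null_fit(m, fwhm = 0)
  sm0 <- estimate_smoothness(fit0, m)
  expect_lt(sm0$fwhm_median, sm10$fwhm_median)
  expect_lt(sm0$fwhm_median, 3 * mean(edge_lengths(m)))
  expect_gt(sm0$fwhm_median, 0.5 * mean(edge_lengths(m)))
  # resel total for an isotropic field within a factor 1.5 of the
  # closed-form area / FWHM^2
  iso <- sum(face_areas(m)) / 10^2
  expect_lt(sm10$total_resels / iso, 1.5)
  expect_gt(sm10$total_resels / iso, 1 / 1.5)
})

test_that("identical residuals along an edge contribute zero roughness", {
  m <- triangle_mesh()
  # vertices 1 and 2 share the same residual vector; vertex 3 differs
  r <- cbind(c(1, -1, 2, 0), c(1, -1, 2, 0), c(0, 2, -1, 1))
  fit <- structure(list(residuals = r, df_resid = 3), class = "glm_fit")
  sm <- estimate_smoothness(fit, m)
  # the 1-2 edge has zero difference, so both endpoint FWHMs are driven
  # by their edges to vertex 3 only; no NaN/Inf appears
  expect_true(all(is.finite(sm$local_fwhm)))
  e <- mesh_edges(m)
  expect_equal(sm$resels_per_face, 0)  # degenerate triangle: zero area
})

test_that("cluster extraction equals the flood-fill oracle", {
  m <- make_icosphere(2)
  adj <- build_adjacency(m)
  set.seed(91)
  for (rep in 1:5) {
    x <- rnorm(m$V)
    stat <- stat_map(x, "t", 50)
    cl <- extract_clusters(stat, m, forming_p = 0.1, tail = "positive")
    thr <- qt(0.9, 50)
    oracle <- flood_fill_oracle(adj, which(x > thr))
    got <- lapply(cl$membership, sort)
    expect_equal(length(got), length(oracle))
    expect_setequal(vapply(got, paste, collapse = ",", ""),
                    vapply(oracle, paste, collapse = ",", ""))
  }
  # all-zero map -> empty set, not an error
  empty <- extract_clusters(stat_map(numeric(m$V), "t", 50), m, 0.05)
  expect_equal(nrow(empty$clusters), 0)
  # two supra-threshold islands separated by a sub-threshold ring
  d <- hop_distances(adj, 1)
  far <- which.max(d)
  x2 <- numeric(m$V)
  x2[d <= 1] <- 10
  x2[hop_distances(adj, far) <= 1] <- 10
  cl2 <- extract_clusters(stat_map(x2, "t", 50), m, 0.001)
  expect_equal(nrow(cl2$clusters), 2)
})

test_that("stricter forming thresholds give nested clusters", {
  m <- make_icosphere(2)
  set.seed(101)
  x <- smooth_field(m, rnorm(m$V) * 5, 15)
  stat <- stat_map(x, "t", 40)
  lax <- extract_clusters(stat, m, forming_p = 0.1)
  strict <- extract_clusters(stat, m, forming_p = 0.01)
  lax_union <- unlist(lax$membership)
  for (vs in strict$membership) expect_true(all(vs %in% lax_union))
})

test_that("cluster p-values respect degenerate extents and search-region size", {
  m <- make_icosphere(3)
  fit <- null_fit(m, fwhm = 10, seed = 111)
  sm <- estimate_smoothness(fit, m)
  tmap <- contrast_t(fit, c(0, 1))
  cl <- extract_clusters(tmap, m, forming_p = 0.05)
  cl <- cluster_pvalues(cl, sm)
  expect_true(all(cl$clusters$p_cluster > 0 & cl$clusters$p_cluster <= 1))
  # doubling the search region makes every cluster less significant
  cl2 <- cluster_pvalues(cl, sm, search_resels = 2 * sm$total_resels)
  big <- cl$clusters$p_cluster < 1
  expect_true(all(cl2$clusters$p_cluster[big] >
                    cl$clusters$p_cluster[big]))
  # zero-extent clusters are never significant
  sm0 <- sm
  sm0$vertex_resels <- numeric(m$V)
  cl0 <- cluster_pvalues(cl, sm0)
  expect_true(all(cl0$clusters$p_cluster == 1))
})

test_that("significance masks nest over cluster alphas and recover planted signal", {
  m <- make_icosphere(3)
  coh <- generate_cohort(31, 31, seed = 121)
  ef <- effect_spec("CT", 42, 6, effect_size = 2.5, sign = 1)
  gm <- generate_measures(m, coh, list(ef), seed = 121)
  Y <- smooth_field(m, gm$ct, 10)
  fit <- fit_ols(Y, build_design(coh, age_order = 2))
  sm <- estimate_smoothness(fit, m)
  tmap <- contrast_t(fit, "group")
  masks <- lapply(c(0.001, 0.01, 0.05), function(a) {
    significant_mask(tmap, m, sm, cluster_alpha = a, forming_p = 0.001)
  })
  expect_true(all(which(masks[[1]] != 0) %in% which(masks[[2]] != 0)))
  expect_true(all(which(masks[[2]] != 0) %in% which(masks[[3]] != 0)))
  # the planted thickness increase is recovered with positive sign
  inside <- gm$truth$ct_effect_mask != 0
  expect_gt(sum(masks[[3]][inside] == 1), 0)
  cl <- attr(masks[[3]], "clusters")
  expect_true(any(inside[cl$peak_vertex] & cl$sign == 1))
})

test_that("F-field cluster inference works for model-selection maps", {
  m <- make_icosphere(2)
  coh <- generate_cohort(30, 30, seed = 131)
  set.seed(131)
  Y <- smooth_field(m, matrix(rnorm(nrow(coh) * m$V), nrow(coh), m$V), 10)
  fr <- fit_ols(Y, build_design(coh, age_order = 1))
  ff <- fit_ols(Y, build_design(coh, age_order = 2))
  fmap <- nested_f(fr, ff)
  expect_error(extract_clusters(fmap, m, 0.05, tail = "negative"),
               "negative tail")
  cl <- extract_clusters(fmap, m, forming_p = 0.05)
  sm <- estimate_smoothness(ff, m)
  cl <- cluster_pvalues(cl, sm, two_tailed = FALSE)
  expect_true(all(cl$clusters$p_cluster > 0 & cl$clusters$p_cluster <= 1))
})
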