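## Random-field-theory cluster inference on triangulated surfaces.
##
## Smoothness is estimated from normalized GLM residuals: for each mesh
## edge the summed squared difference of the unit-norm residual vectors
## estimates 2(1 - rho), which for a Gaussian autocorrelation equals
## lambda * h^2 with lambda the derivative variance of the field and h the
## edge length; FWHM = sqrt(4 ln 2 / lambda). Triangle areas re-expressed
## in FWHM units (via Heron's formula on the normalized edge lengths) give
## resolution elements (resels). Cluster-level familywise p-values come
## from the expected-cluster framework for smooth random fields: with R
## search-region resels and forming threshold u, the expected cluster
## count is E[m] = R * rho2(u), the expected suprathreshold resel area is
## R * P(T > u), cluster resel extents are approximately exponential with
## rate beta = rho2(u) / P(T > u), and
## P(FWE) = 1 - exp(-E[m] * exp(-beta * k)).

#' Two-dimensional Euler characteristic densities
#'
#' Resel-scaled EC densities for t and F random fields, the leading term
#' of expected-cluster-count calculations on surfaces.
#'
#' @param u field threshold (t value, or F value for `kind = "F"`).
#' @param df degrees of freedom: scalar (t) or `c(df1, df2)` (F).
#' @param kind `"t"` or `"F"`.
#' @return EC density per resel (can be negative for F below the mode;
#'   callers clamp at 0 when using it as an expected count).
#' @export
ec_density_2d <- function(u, df, kind = c("t", "F")) {
  kind <- match.arg(kind)
  if (kind == "t") {
    nu <- df[1L]
    (4 * log(2)) / (2 * pi)^1.5 *
      exp(lgamma((nu + 1) / 2) - lgamma(nu / 2)) / sqrt(nu / 2) *
      u * (1 + u^2 / nu)^(-(nu - 1) / 2)
  } else {
    k <- df[1L]; nu <- df[2L]
    (4 * log(2)) / (2 * pi) *
      exp(lgamma((nu + k - 2) / 2) - lgamma(nu / 2) - lgamma(k / 2)) *
      (k * u / nu)^((k - 2) / 2) * (1 + k * u / nu)^(-(nu + k - 2) / 2) *
      ((nu - 1) * k * u / nu - (k - 1))
  }
}

stat_tail_p <- function(u, df, kind) {
  if (kind == "t") stats::pt(u, df[1L], lower.tail = FALSE)
  else stats::pf(u, df[1L], df[2L], lower.tail = FALSE)
}

stat_quantile <- function(p, df, kind) {
  if (kind == "t") stats::qt(p, df[1L], lower.tail = FALSE)
  else stats::qf(p, df[1L], df[2L], lower.tail = FALSE)
}

#' Estimate residual field smoothness on a mesh
#'
#' Normalizes the residual vector at each vertex to unit length, sums
#' squared differences of the normalized residuals along each mesh edge,
#' and converts the implied correlation decay to a local FWHM and per-face
#' resel density (see the file header for the estimator's derivation).
#' Vertices with zero residual variance are excluded from resel sums and
#' get `NA` local FWHM.
#'
#' @param fit a `glm_fit`.
#' @param mesh the `surf_mesh` the fit's vertices live on.
#' @return a `smoothness_field`: `local_fwhm` (per vertex, mm),
#'   `resels_per_face`, `vertex_resels`, `total_resels`, `fwhm_median`.
#' @export
estimate_smoothness <- function(fit, mesh) {
  if (fit$df_resid < 3) stop("need at least 3 residual df")
  r <- fit$residuals
  norms <- sqrt(colSums(r^2))
  ok <- norms > 0
  u <- r
  u[, ok] <- sweep(r[, ok, drop = FALSE], 2, norms[ok], "/")

  e <- mesh_edges(mesh)
  h <- edge_lengths(mesh, e)
  good_edge <- ok[e[, 1L]] & ok[e[, 2L]]
  du2 <- colSums((u[, e[, 1L], drop = FALSE] -
                    u[, e[, 2L], drop = FALSE])^2)
  du2[!good_edge] <- NA_real_
  lambda_edge <- du2 / h^2

  # per-vertex FWHM from mean incident-edge roughness
  lam_v <- numeric(mesh$V); cnt <- numeric(mesh$V)
  for (k in 1:2) {
    idx <- e[good_edge, k]
    s <- tapply(lambda_edge[good_edge], idx, sum)
    n_ <- tapply(rep(1, sum(good_edge)), idx, sum)
    vi <- as.integer(names(s))
    lam_v[vi] <- lam_v[vi] + s
    cnt[vi] <- cnt[vi] + n_
  }
  local_fwhm <- rep(NA_real_, mesh$V)
  has <- cnt > 0 & lam_v > 0
  local_fwhm[has] <- sqrt(4 * log(2) * cnt[has] / lam_v[has])

  # face resels: Heron's formula on edge lengths in FWHM units
  ekey <- paste(e[, 1L], e[, 2L])
  resl <- du2 / (4 * log(2))   # squared edge length in FWHM^2 units
  names(resl) <- ekey
  f <- mesh$faces
  fk <- function(i, j) paste(pmin(f[, i], f[, j]), pmax(f[, i], f[, j]))
  a2 <- resl[fk(1, 2)]; b2 <- resl[fk(2, 3)]; c2 <- resl[fk(1, 3)]
  # Heron in squared-length form: 16 A^2 = 4 a2 b2 - (a2 + b2 - c2)^2
  s16 <- 4 * a2 * b2 - (a2 + b2 - c2)^2
  resels_face <- ifelse(is.na(s16) | s16 < 0, 0, sqrt(pmax(s16, 0)) / 4)

  vertex_resels <- numeric(mesh$V)
  for (k in 1:3) {
    s <- tapply(resels_face, f[, k], sum)
    vi <- as.integer(names(s))
    vertex_resels[vi] <- vertex_resels[vi] + s
  }
  structure(list(local_fwhm = local_fwhm,
                 resels_per_face = unname(resels_face),
                 vertex_resels = vertex_resels / 3,
                 total_resels = sum(resels_face),
                 fwhm_median = stats::median(local_fwhm, na.rm = TRUE)),
            class = "smoothness_field")
}

#' @export
print.smoothness_field <- function(x, ...) {
  cat(sprintf("smoothness_field: median FWHM %.2f mm, %.2f resels\n",
              x$fwhm_median, x$total_resels))
  invisible(x)
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Converts the vertex-level forming threshold `forming_p` to a statistic
#' cutoff at the map's degrees of freedom, and finds connected components
#' of supra-threshold vertices over the mesh adjacency. Cluster surface
#' extent sums the per-vertex tessellation areas (one-ring face-area
#' thirds).
#'
#' @param stat a `stat_map`.
#' @param mesh the `surf_mesh`.
#' @param forming_p vertex-level tail probability defining the cutoff
#'   (per tail).
#' @param tail `"positive"` (values above the cutoff) or `"negative"`
#'   (t maps only).
#' @return a `cluster_set`: data.frame `clusters` (cluster id, peak
#'   vertex, peak stat, n vertices, extent mm^2, sign) plus `membership`
#'   (list of vertex-id vectors), the forming threshold used, `tail`,
#'   `kind` and `df`.
#' @export
extract_clusters <- function(stat, mesh, forming_p = 0.001,
                             tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  stopifnot(inherits(stat, "stat_map"), forming_p > 0, forming_p < 1)
  if (stat$kind == "F" && tail == "negative") {
    stop("F maps have no negative tail")
  }
  thresh <- stat_quantile(forming_p, stat$df, stat$kind)
  x <- stat$statistic
  if (length(x) != mesh$V) stop("stat map length does not match mesh")
  supra <- if (tail == "positive") which(x > thresh) else which(x < -thresh)
  empty <- list(
    clusters = data.frame(cluster = integer(), peak_vertex = integer(),
                          peak_stat = numeric(), n_vertices = integer(),
                          extent_mm2 = numeric(), extent_resels = numeric(),
                          p_cluster = numeric(), sign = integer()),
    membership = list(), forming_threshold = thresh, forming_p = forming_p,
    tail = tail, kind = stat$kind, df = stat$df)
  class(empty) <- "cluster_set"
  if (!length(supra)) return(empty)

  g <- igraph::induced_subgraph(mesh_graph_cached(mesh), supra)
  comp <- igraph::components(g)
  membership <- split(supra, comp$membership)
  va <- vertex_areas(mesh)
  sgn <- if (tail == "positive") 1L else -1L
  rows <- lapply(seq_along(membership), function(i) {
    vs <- membership[[i]]
    pk <- vs[which.max(abs(x[vs]))]
    data.frame(cluster = i, peak_vertex = pk, peak_stat = x[pk],
               n_vertices = length(vs), extent_mm2 = sum(va[vs]),
               extent_resels = NA_real_, p_cluster = NA_real_, sign = sgn)
  })
  out <- empty
  out$clusters <- do.call(rbind, rows)
  out$membership <- membership
  out
}

# igraph construction dominates repeated cluster extraction on a fixed
# template; memoise per mesh object within a session.
mesh_graph_env <- new.env(parent = emptyenv())
mesh_graph_cached <- function(mesh) {
  key <- paste0(mesh$V, "_", mesh$F, "_",
                sum(mesh$faces[1L, ]), "_", mesh$hemisphere)
  g <- mesh_graph_env[[key]]
  if (is.null(g)) {
    g <- igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE)
    mesh_graph_env[[key]] <- g
  }
  g
}

#' Assign RFT familywise p-values to clusters
#'
#' Computes each cluster's extent in resels from the smoothness field and
#' applies the expected-cluster approximation (see file header). For
#' two-tailed analyses the per-tail p is doubled (Bonferroni over tails)
#' and capped at 1. A cluster of zero resel extent gets p = 1.
#'
#' @param clusters a `cluster_set` from [extract_clusters()].
#' @param smooth a `smoothness_field` for the same fit/mesh.
#' @param search_resels resels of the whole search region; defaults to
#'   `smooth$total_resels`. Pass the summed value when several
#'   hemispheres form one familywise search region.
#' @param two_tailed double the per-tail p (the default for t maps).
#' @return the `cluster_set` with `extent_resels` and `p_cluster` filled.
#' @export
cluster_pvalues <- function(clusters, smooth,
                            search_resels = smooth$total_resels,
                            two_tailed = clusters$kind == "t") {
  df <- clusters$df
  if (any(df <= 0)) stop("degrees of freedom must be positive")
  u <- clusters$forming_threshold
  rho2 <- max(ec_density_2d(u, df, clusters$kind), 0)
  p0 <- stat_tail_p(u, df, clusters$kind)
  em <- search_resels * rho2
  beta <- if (p0 > 0) rho2 / p0 else Inf
  tbl <- clusters$clusters
  if (nrow(tbl)) {
    k <- vapply(clusters$membership,
                function(vs) sum(smooth$vertex_resels[vs]), numeric(1))
    tbl$extent_resels <- unname(k)
    p_tail <- ifelse(k <= 0, 1, 1 - exp(-em * exp(-beta * k)))
    tbl$p_cluster <- pmin(1, if (two_tailed) 2 * p_tail else p_tail)
    clusters$clusters <- tbl
  }
  clusters$search_resels <- search_resels
  clusters
}

#' Signed mask of cluster-corrected significant vertices
#'
#' Runs the positive and negative tail cluster analyses and keeps clusters
#' with familywise p at or below `cluster_alpha`; the mask holds the
#' cluster's sign at member vertices and 0 elsewhere.
#'
#' @param stat a t `stat_map`.
#' @param mesh the `surf_mesh`.
#' @param smooth a `smoothness_field`.
#' @param cluster_alpha cluster-level (two-tailed) significance.
#' @param forming_p per-tail vertex-level forming threshold.
#' @param search_resels familywise search-region resels (see
#'   [cluster_pvalues()]).
#' @return integer vector of length V in `{-1, 0, 1}` with attributes
#'   `clusters` (the combined significant `cluster_set` tables) and
#'   `provenance`.
#' @export
significant_mask <- function(stat, mesh, smooth, cluster_alpha = 0.05,
                             forming_p = 0.001,
                             search_resels = smooth$total_resels) {
  mask <- integer(mesh$V)
  kept <- list()
  tails <- if (stat$kind == "t") c("positive", "negative") else "positive"
  for (tl in tails) {
    cs <- extract_clusters(stat, mesh, forming_p, tl)
    cs <- cluster_pvalues(cs, smooth, search_resels,
                          two_tailed = stat$kind == "t")
    sig <- which(cs$clusters$p_cluster <= cluster_alpha)
    for (i in sig) {
      mask[cs$membership[[i]]] <- cs$clusters$sign[i]
    }
    if (length(sig)) kept[[tl]] <- cs$clusters[sig, , drop = FALSE]
  }
  attr(mask, "clusters") <- do.call(rbind, kept)
  attr(mask, "provenance") <- list(contrast = stat$contrast,
                                   cluster_alpha = cluster_alpha,
                                   forming_p = forming_p)
  mask
}
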