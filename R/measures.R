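#' Planted effect cluster specification
#'
#' Describes one circular (k-ring) patch of group difference planted into
#' the synthetic vertex measures: which feature it perturbs, where, how
#' far it extends in adjacency hops, its standardized amplitude, its sign,
#' and an optional age-by-group interaction slope inside the patch.
#'
#' @param feature `"CT"` or `"SA"`.
#' @param seed_vertex patch centre (vertex index).
#' @param radius_hops patch radius in adjacency hops (>= 0).
#' @param effect_size Cohen's d of the case-control shift relative to the
#'   residual vertex noise sd.
#' @param sign `+1` (case > control) or `-1`.
#' @param age_interaction_slope per-year change of the group difference
#'   (same standardized units per year).
#' @return an `effect_spec` object.
#' @export
effect_spec <- function(feature = c("CT", "SA"), seed_vertex, radius_hops,
                        effect_size, sign = 1, age_interaction_slope = 0) {
  feature <- match.arg(feature)
  stopifnot(radius_hops >= 0, sign %in% c(-1, 1), effect_size >= 0)
  structure(list(feature = feature, seed_vertex = as.integer(seed_vertex),
                 radius_hops = as.integer(radius_hops),
                 effect_size = effect_size, sign = sign,
                 age_interaction_slope = age_interaction_slope),
            class = "effect_spec")
}

effect_mask_vertices <- function(adj, spec) {
  d <- hop_distances(adj, spec$seed_vertex)
  which(d <= spec$radius_hops)
}

# Smoothed unit-variance noise: iid N(0,1) per vertex smoothed to the
# requested FWHM, then rescaled so the realized per-vertex sd is 1 again
# (smoothing shrinks variance; effect sizes are stated relative to the
# post-smoothing noise scale).
smoothed_unit_noise <- function(mesh, n, fwhm_mm, op) {
  z <- matrix(stats::rnorm(n * mesh$V), n, mesh$V)
  if (fwhm_mm > 0) {
    z <- smooth_field(mesh, z, fwhm_mm, op = op)
    z <- z / stats::sd(as.numeric(z))
  }
  z
}

#' Generate per-vertex CT/SA/CV measures for a cohort
#'
#' Builds subjects-by-vertices matrices with the structure the vertex-wise
#' analysis assumes: a per-subject baseline, a quadratic age trend shared
#' by both groups, planted group-difference patches from `effects`, and
#' spatially smooth Gaussian noise. Surface area is generated on the log
#' scale, scaled by each subject's total surface area; cortical volume is
#' the per-vertex product `CV = CT * SA` with optional multiplicative
#' log-normal noise, so volume effects are emergent from the thickness and
#' area fields rather than planted directly.
#'
#' @param mesh a `surf_mesh`.
#' @param cohort a `cohort_table`.
#' @param effects list of [effect_spec()] objects (may be empty).
#' @param noise_fwhm_mm smoothness of the vertex noise fields, mm.
#' @param seed integer seed.
#' @param ct_noise_sd residual CT sd per vertex, mm.
#' @param sa_noise_sd residual log-SA sd per vertex.
#' @param ct_age quadratic age trend for CT: `c(linear, quadratic)` in
#'   mm/year and mm/year^2, applied to age centered within the cohort.
#' @param sa_age quadratic age trend for log-SA per year and year^2.
#' @param cv_noise_sd sd of the multiplicative log-normal CV noise
#'   (0 disables it, making CV exactly CT * SA).
#' @return list with matrices `ct` (mm), `sa` (mm^2), `cv` (mm^3) of size
#'   n x V, and `truth` holding signed `ct_effect_mask` / `sa_effect_mask`
#'   vectors and the per-vertex generating amplitudes (`parameters`).
#' @export
generate_measures <- function(mesh, cohort, effects = list(),
                              noise_fwhm_mm = 10, seed = 1,
                              ct_noise_sd = 0.25, sa_noise_sd = 0.10,
                              ct_age = c(-0.015, -2e-3),
                              sa_age = c(-0.004, -4e-4),
                              cv_noise_sd = 0.02) {
  stopifnot(inherits(mesh, "surf_mesh"), nrow(cohort) > 0)
  for (ef in effects) {
    if (ef$seed_vertex < 1 || ef$seed_vertex > mesh$V) {
      stop("effect seed_vertex ", ef$seed_vertex, " out of range [1, ",
           mesh$V, "]")
    }
  }
  adj <- build_adjacency(mesh)
  op <- smoothing_operator(mesh)
  n <- nrow(cohort)
  V <- mesh$V
  grp <- as.numeric(cohort$group == "case")
  cage <- cohort$age - mean(cohort$age)

  masks <- list(CT = numeric(V), SA = numeric(V))
  amps <- list(CT = numeric(V), SA = numeric(V))
  slopes <- list(CT = numeric(V), SA = numeric(V))
  sds <- c(CT = ct_noise_sd, SA = sa_noise_sd)
  for (ef in effects) {
    idx <- effect_mask_vertices(adj, ef)
    masks[[ef$feature]][idx] <- ef$sign
    amps[[ef$feature]][idx] <- ef$sign * ef$effect_size * sds[[ef$feature]]
    slopes[[ef$feature]][idx] <-
      ef$age_interaction_slope * sds[[ef$feature]]
  }

  with_seed(seed, {
    ct_trend <- outer(cage, rep(ct_age[1], V)) +
      outer(cage^2, rep(ct_age[2], V))
    ct <- matrix(cohort$mean_ct, n, V) + ct_trend +
      grp %*% t(amps$CT) + (grp * cage) %*% t(slopes$CT) +
      ct_noise_sd * smoothed_unit_noise(mesh, n, noise_fwhm_mm, op)

    va <- vertex_areas(mesh)
    log_base <- outer(log(cohort$total_sa * 1e6), log(va / sum(va)), `+`)
    log_sa <- log_base +
      outer(cage, rep(sa_age[1], V)) + outer(cage^2, rep(sa_age[2], V)) +
      grp %*% t(amps$SA) + (grp * cage) %*% t(slopes$SA) +
      sa_noise_sd * smoothed_unit_noise(mesh, n, noise_fwhm_mm, op)
    sa <- exp(log_sa)

    cv <- ct * sa
    if (cv_noise_sd > 0) {
      cv <- cv * exp(matrix(stats::rnorm(n * V, 0, cv_noise_sd), n, V))
    }

    list(ct = ct, sa = sa, cv = cv,
         truth = list(ct_effect_mask = masks$CT,
                      sa_effect_mask = masks$SA,
                      parameters = list(ct_amplitude = amps$CT,
                                        sa_amplitude = amps$SA)))
  })
}

#' Build a CT/SA effect pair with a prescribed spatial overlap
#'
#' Returns a thickness-increase and an area-decrease patch whose truth
#' masks overlap in a requested fraction of their union (Jaccard), the
#' scenario used to probe the overlap statistic. The area patch centre is
#' searched over hop-distance rings from the thickness patch centre; the
#' achievable fractions are discrete, so the best candidate within one
#' adjacency ring of the target is returned.
#'
#' @param mesh a `surf_mesh`.
#' @param overlap_fraction target `|A intersect B| / |A union B|` in
#'   `[0, 1]`.
#' @param seed integer seed (chooses the thickness patch centre).
#' @param radius_hops patch radius for both effects.
#' @param effect_size Cohen's d for both effects.
#' @return list of two [effect_spec()]: CT with sign `+1`, SA with
#'   sign `-1`.
#' @export
plant_overlap_scenario <- function(mesh, overlap_fraction, seed = 1,
                                   radius_hops = 6, effect_size = 1.5) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  adj <- build_adjacency(mesh)
  ct_seed <- with_seed(seed, sample.int(mesh$V, 1))
  d_ct <- hop_distances(adj, ct_seed)
  disk_ct <- which(d_ct <= radius_hops)

  jaccard_at <- function(sa_seed) {
    disk_sa <- which(hop_distances(adj, sa_seed) <= radius_hops)
    length(intersect(disk_ct, disk_sa)) / length(union(disk_ct, disk_sa))
  }
  # candidate centres: one per hop ring out to well beyond disjointness
  max_d <- max(d_ct[is.finite(d_ct)])
  cand <- vapply(0:max_d, function(dd) which(d_ct == dd)[1L], integer(1))
  jac <- vapply(cand, jaccard_at, numeric(1))
  best <- which.min(abs(jac - overlap_fraction))

  # one-ring tolerance: the step to the neighbouring candidate rings
  steps <- abs(diff(jac))
  local <- steps[intersect(c(best - 1L, best), seq_along(steps))]
  ring_tol <- max(local, 1 / length(disk_ct))
  if (abs(jac[best] - overlap_fraction) > ring_tol + 1e-9) {
    stop("overlap fraction ", overlap_fraction, " unreachable on this ",
         "mesh (closest achievable ", round(jac[best], 3),
         "); try a larger radius_hops")
  }
  list(
    effect_spec("CT", ct_seed, radius_hops, effect_size, sign = 1),
    effect_spec("SA", cand[best], radius_hops, effect_size, sign = -1)
  )
}
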