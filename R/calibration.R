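## Monte-Carlo calibration of the cluster-inference pipeline: familywise
## error on null synthetic cohorts, and recovery of planted effects.
## These run the same generator -> smooth -> GLM -> smoothness -> cluster
## path as the pipeline, at a reduced mesh scale chosen to keep a
## 1000-replicate null study at desk scale.

#' Familywise error rate of cluster inference on null cohorts
#'
#' Repeatedly generates a cohort with no planted effects, runs the
#' thickness analysis (smoothing, full GLM, smoothness estimation, signed
#' cluster mask at the given thresholds), and reports the fraction of
#' replicates with any significant cluster. Under a calibrated procedure
#' this approximates `cluster_alpha`.
#'
#' @param n_sims number of null replicates.
#' @param seed integer seed; replicate `i` uses `seed + i` offsets.
#' @param subdivisions,mesh_radius icosphere template parameters.
#' @param n_case,n_control group sizes.
#' @param fwhm_mm analysis smoothing FWHM (also the generator's noise
#'   smoothness).
#' @param cluster_alpha,forming_p inference thresholds.
#' @return list with `fwe` (proportion of replicates with any significant
#'   cluster), `n_sims`, and the per-replicate logical vector `any_sig`.
#' @export
fwe_null_rate <- function(n_sims = 1000, seed = 1, subdivisions = 3,
                          mesh_radius = 50, n_case = 20, n_control = 20,
                          fwhm_mm = 10, cluster_alpha = 0.05,
                          forming_p = 0.001) {
  mesh <- make_icosphere(subdivisions, mesh_radius)
  op <- smoothing_operator(mesh)
  any_sig <- vapply(seq_len(n_sims), function(i) {
    # null condition: identical mean-CT distributions in the two groups
    # (the cohort defaults give cases a 0.01 mm lower baseline)
    cohort <- generate_cohort(n_case, n_control, seed = seed + i,
                              mean_ct_case = c(2.72, 0.13),
                              mean_ct_control = c(2.72, 0.13))
    gm <- generate_measures(mesh, cohort, effects = list(),
                            noise_fwhm_mm = fwhm_mm, seed = seed + i)
    Y <- smooth_field(mesh, gm$ct, fwhm_mm, op = op)
    fit <- fit_ols(Y, build_design(cohort, age_order = 2))
    sm <- estimate_smoothness(fit, mesh)
    mask <- significant_mask(contrast_t(fit, "group"), mesh, sm,
                             cluster_alpha = cluster_alpha,
                             forming_p = forming_p)
    any(mask != 0)
  }, logical(1))
  list(fwe = mean(any_sig), n_sims = n_sims, any_sig = any_sig)
}

#' Recovery of planted thickness/area effect clusters
#'
#' For each seed, plants a thickness-increase and an area-decrease patch
#' (via [plant_overlap_scenario()]), runs the analysis path, and checks
#' that each feature yields at least one significant cluster of the
#' planted sign whose peak vertex lies inside the corresponding truth
#' mask.
#'
#' @param seeds integer vector of seeds, one replicate each.
#' @param effect_size planted Cohen's d.
#' @param n_case,n_control group sizes.
#' @param subdivisions,mesh_radius icosphere template parameters.
#' @param radius_hops planted patch radius.
#' @param overlap_fraction planted CT/SA mask overlap (Jaccard).
#' @param fwhm_mm smoothing / noise FWHM.
#' @param cluster_alpha,forming_p inference thresholds.
#' @return data.frame with one row per seed: `ct_recovered`,
#'   `sa_recovered` (sign-correct peak inside the truth mask), and the
#'   realized `overlap_pct` of the significant CT/SA masks.
#' @export
effect_recovery <- function(seeds = 1:20, effect_size = 1.5,
                            n_case = 62, n_control = 57,
                            subdivisions = 3, mesh_radius = 50,
                            radius_hops = 6, overlap_fraction = 0.2,
                            fwhm_mm = 10, cluster_alpha = 0.05,
                            forming_p = 0.001) {
  mesh <- make_icosphere(subdivisions, mesh_radius)
  op <- smoothing_operator(mesh)
  rows <- lapply(seeds, function(s) {
    effects <- plant_overlap_scenario(mesh, overlap_fraction, seed = s,
                                      radius_hops = radius_hops,
                                      effect_size = effect_size)
    cohort <- generate_cohort(n_case, n_control, seed = s)
    gm <- generate_measures(mesh, cohort, effects,
                            noise_fwhm_mm = fwhm_mm, seed = s + 1000)
    check <- function(Y, truth_mask, want_sign) {
      fit <- fit_ols(smooth_field(mesh, Y, fwhm_mm, op = op),
                     build_design(cohort, age_order = 2))
      sm <- estimate_smoothness(fit, mesh)
      mask <- significant_mask(contrast_t(fit, "group"), mesh, sm,
                               cluster_alpha = cluster_alpha,
                               forming_p = forming_p)
      cl <- attr(mask, "clusters")
      ok <- FALSE
      if (!is.null(cl) && nrow(cl)) {
        ok <- any(cl$sign == want_sign &
                    truth_mask[cl$peak_vertex] == want_sign)
      }
      list(ok = ok, mask = mask)
    }
    ct <- check(gm$ct, gm$truth$ct_effect_mask, 1L)
    sa <- check(gm$sa, gm$truth$sa_effect_mask, -1L)
    both <- sum(ct$mask != 0 & sa$mask != 0)
    either <- sum(ct$mask != 0 | sa$mask != 0)
    t_both <- sum(gm$truth$ct_effect_mask != 0 &
                    gm$truth$sa_effect_mask != 0)
    t_either <- sum(gm$truth$ct_effect_mask != 0 |
                      gm$truth$sa_effect_mask != 0)
    data.frame(seed = s, ct_recovered = ct$ok, sa_recovered = sa$ok,
               overlap_pct = if (either) 100 * both / either else NA_real_,
               truth_overlap_pct = 100 * t_both / t_either)
  })
  do.call(rbind, rows)
}
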