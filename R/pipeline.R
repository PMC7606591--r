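## End-to-end orchestration: synthesize (or accept) per-vertex measures,
## smooth, select the age model, run group and age-by-group contrasts,
## RFT-correct at each cluster threshold, and feed the signed masks into
## the overlap and volume-decomposition statistics.

default_config <- function() {
  list(
    seed = 1,
    smoothing_fwhm_mm = 10,
    synthetic = list(
      mesh_subdivisions = 3, mesh_radius = 50,
      n_case = 62, n_control = 57, age_range = c(6, 31),
      overlap_fraction = 0.2, radius_hops = 6, effect_size = 1.5,
      noise_fwhm_mm = 10
    ),
    model = list(age_order = 0, selection_alpha = 0.05,
                 with_interactions = TRUE, include_iq = TRUE),
    inference = list(forming_p = 0.001,
                     cluster_alphas = c(0.05, 0.01, 0.001)),
    overlap = list(alpha = 0.05, n_sims = 1000)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list; unspecified entries fall
#' back to documented defaults, and the fully resolved configuration is
#' what gets echoed into the run manifest.
#'
#' @param config YAML path or list (possibly partial).
#' @return the effective configuration list.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  stopifnot(cfg$inference$forming_p > 0, cfg$inference$forming_p < 1,
            all(cfg$inference$cluster_alphas > 0),
            all(cfg$inference$cluster_alphas < 1))
  cfg
}

threshold_label <- function(alpha) paste0("p<", format(alpha))

synthesize_study <- function(cfg) {
  sy <- cfg$synthetic
  hemis <- c("left", "right")
  meshes <- lapply(hemis, function(h) {
    make_icosphere(sy$mesh_subdivisions, sy$mesh_radius, hemisphere = h)
  })
  names(meshes) <- hemis
  cohort <- generate_cohort(sy$n_case, sy$n_control, sy$age_range,
                            seed = cfg$seed)
  measures <- list(); truth <- list(); effects <- list()
  for (i in seq_along(hemis)) {
    h <- hemis[i]
    ef <- if (sy$effect_size > 0) {
      plant_overlap_scenario(meshes[[h]], sy$overlap_fraction,
                             seed = cfg$seed + i,
                             radius_hops = sy$radius_hops,
                             effect_size = sy$effect_size)
    } else list()
    effects[[h]] <- ef
    gm <- generate_measures(meshes[[h]], cohort, ef,
                            noise_fwhm_mm = sy$noise_fwhm_mm,
                            seed = cfg$seed + 100 + i)
    measures[[h]] <- gm[c("ct", "sa", "cv")]
    truth[[h]] <- gm$truth
  }
  list(meshes = meshes, cohort = cohort, measures = measures,
       truth = truth, effects = effects)
}

#' Run the full surface morphometry pipeline
#'
#' Stages: (1) load or synthesize cohort and per-vertex measures;
#' (2) surface-smooth each measure; (3) step-up age-model selection on
#' the combined sample; (4) group and age-by-group contrasts for CT, SA
#' and CV with the adopted model; (5) RFT cluster-corrected signed masks
#' at each configured cluster threshold (hemispheres are separate search
#' regions whose resels are summed); (6) CT/SA overlap tables with the
#' chi-square test and the simulation null; (7) CV decomposition;
#' (8) global cohort statistics. Deterministic given the config seed.
#'
#' @param config YAML path or list, see [read_run_config()].
#' @param data optional precomputed study (as returned by the internal
#'   synthesizer: `meshes`, `cohort`, `measures` per hemisphere); when
#'   supplied the synthetic block is ignored.
#' @return a `result_bundle` list with elements `config`, `cohort`,
#'   `selection`, `stat_maps`, `smoothness`, `masks`, `overlap_tables`,
#'   `chi2`, `null_overlap`, `decomposition_tables`, `global_stats`,
#'   `truth`, `effects`.
#' @export
run_pipeline <- function(config = list(), data = NULL) {
  cfg <- read_run_config(config)
  stage <- "load-data"
  bundle <- try({
    study <- if (is.null(data)) synthesize_study(cfg) else data
    hemis <- names(study$meshes)
    features <- c("ct", "sa", "cv")

    stage <- "smooth"
    ops <- lapply(study$meshes, smoothing_operator)
    smoothed <- lapply(hemis, function(h) {
      lapply(study$measures[[h]], function(Y) {
        smooth_field(study$meshes[[h]], Y, cfg$smoothing_fwhm_mm,
                     op = ops[[h]])
      })
    })
    names(smoothed) <- hemis

    stage <- "model-selection"
    if (cfg$model$age_order %in% 1:3) {
      adopted <- cfg$model$age_order
      selection <- list(adopted_order = adopted, forced = TRUE)
    } else {
      sel_runs <- list()
      for (h in hemis) for (f in features) {
        sel_runs[[paste(h, f)]] <- stepup_select(
          smoothed[[h]][[f]], study$cohort, study$meshes[[h]],
          cluster_alpha = cfg$model$selection_alpha,
          forming_p = cfg$inference$forming_p,
          with_interactions = cfg$model$with_interactions,
          include_iq = cfg$model$include_iq)
      }
      adopted <- max(vapply(sel_runs, `[[`, integer(1), "adopted_order"))
      selection <- list(adopted_order = adopted, runs = sel_runs,
                        forced = FALSE)
    }

    stage <- "contrasts"
    design <- build_design(study$cohort, age_order = adopted,
                           with_interactions = cfg$model$with_interactions,
                           include_iq = cfg$model$include_iq)
    fits <- lapply(hemis, function(h) {
      lapply(smoothed[[h]], function(Y) fit_ols(Y, design))
    })
    names(fits) <- hemis
    smoothness <- lapply(hemis, function(h) {
      lapply(fits[[h]], estimate_smoothness, mesh = study$meshes[[h]])
    })
    names(smoothness) <- hemis
    contrasts <- c(group = "group", age_x_group = "age_x_group")
    if (!cfg$model$with_interactions) contrasts <- contrasts["group"]
    stat_maps <- lapply(hemis, function(h) {
      lapply(features, function(f) {
        lapply(contrasts, function(cn) contrast_t(fits[[h]][[f]], cn))
      }) |> stats::setNames(features)
    })
    names(stat_maps) <- hemis

    stage <- "rft-masks"
    masks <- list()
    for (alpha in cfg$inference$cluster_alphas) {
      lab <- threshold_label(alpha)
      masks[[lab]] <- lapply(features, function(f) {
        search <- sum(vapply(hemis, function(h) {
          smoothness[[h]][[f]]$total_resels
        }, numeric(1)))
        per_h <- lapply(hemis, function(h) {
          significant_mask(stat_maps[[h]][[f]]$group, study$meshes[[h]],
                           smoothness[[h]][[f]], cluster_alpha = alpha,
                           forming_p = cfg$inference$forming_p,
                           search_resels = search)
        })
        stats::setNames(per_h, hemis)
      }) |> stats::setNames(features)
    }

    stage <- "overlap"
    overlap_tables <- list(); chi2 <- list()
    for (lab in names(masks)) {
      overlap_tables[[lab]] <- classify_overlap(
        masks[[lab]]$ct, masks[[lab]]$sa, threshold_label = lab)
      across <- overlap_tables[[lab]]
      idx <- if ("across" %in% across$hemisphere) "across" else
        across$hemisphere[1]
      cts <- across[across$hemisphere == idx & across$measure != "total",
                    "count"]
      chi2[[lab]] <- if (sum(cts) > 0) chi2_equal_distribution(cts)
      else NULL
    }
    lab1 <- threshold_label(cfg$overlap$alpha)
    obs_tab <- overlap_tables[[lab1]]
    if (is.null(obs_tab)) obs_tab <- overlap_tables[[1]]
    hsel <- if ("across" %in% obs_tab$hemisphere) "across" else
      obs_tab$hemisphere[1]
    observed_pct <- obs_tab$pct[obs_tab$hemisphere == hsel &
                                  obs_tab$measure == "both"]
    n_vertices_total <- sum(vapply(study$meshes, `[[`, numeric(1), "V"))
    null_overlap <- simulate_overlap_null(
      n_vertices_total, alpha = cfg$overlap$alpha,
      n_sims = cfg$overlap$n_sims, seed = cfg$seed,
      observed_overlap_pct = observed_pct)

    stage <- "decomposition"
    decomposition_tables <- lapply(names(masks), function(lab) {
      decompose_cv(masks[[lab]]$cv, masks[[lab]]$ct, masks[[lab]]$sa,
                   threshold_label = lab)
    })
    names(decomposition_tables) <- names(masks)

    stage <- "global-stats"
    gstats <- global_stats(study$cohort)

    structure(list(
      config = cfg, cohort = study$cohort, meshes = study$meshes,
      selection = selection, design = design, fits = fits,
      smoothness = smoothness, stat_maps = stat_maps, masks = masks,
      overlap_tables = overlap_tables, chi2 = chi2,
      null_overlap = null_overlap,
      decomposition_tables = decomposition_tables,
      global_stats = gstats, truth = study$truth,
      effects = study$effects
    ), class = "result_bundle")
  }, silent = TRUE)
  if (inherits(bundle, "try-error")) {
    stop("pipeline failed at stage '", stage, "': ",
         attr(bundle, "condition")$message)
  }
  bundle
}

#' Case-only subgroup contrast
#'
#' Reruns the contrast machinery within the case group, replacing the
#' group factor by a subgroup column (e.g. presence of prodromal
#' psychosis symptoms), with the same smoothing, model and inference
#' settings.
#'
#' @param config YAML path or list, see [read_run_config()].
#' @param subgroup_column cohort column with exactly two levels among
#'   cases; every level needs at least 3 subjects.
#' @param data optional precomputed study (see [run_pipeline()]).
#' @return a `result_bundle` restricted to cases, with `masks` keyed by
#'   threshold and feature as in [run_pipeline()].
#' @export
subgroup_contrast <- function(config = list(),
                              subgroup_column = "psychosis_prodromal",
                              data = NULL) {
  cfg <- read_run_config(config)
  study <- if (is.null(data)) synthesize_study(cfg) else data
  if (!subgroup_column %in% names(study$cohort)) {
    stop("configuration error: no cohort column '", subgroup_column, "'")
  }
  keep <- study$cohort$group == "case"
  sub <- study$cohort[keep, , drop = FALSE]
  levels_ <- unique(sub[[subgroup_column]])
  if (length(levels_) < 2) {
    stop("subgroup column has fewer than 2 levels within cases")
  }
  sizes <- table(sub[[subgroup_column]])
  if (any(sizes < 3)) {
    stop("subgroup level(s) with fewer than 3 subjects: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  }
  study$cohort <- sub
  study$measures <- lapply(study$measures, function(ms) {
    lapply(ms, function(Y) Y[keep, , drop = FALSE])
  })
  cfg$model$subgroup_column <- subgroup_column

  hemis <- names(study$meshes)
  features <- c("ct", "sa", "cv")
  smoothed <- lapply(hemis, function(h) {
    lapply(study$measures[[h]], function(Y) {
      smooth_field(study$meshes[[h]], Y, cfg$smoothing_fwhm_mm)
    })
  })
  names(smoothed) <- hemis
  order_ <- if (cfg$model$age_order %in% 1:3) cfg$model$age_order else 2
  design <- build_design(sub, age_order = order_,
                         with_interactions = cfg$model$with_interactions,
                         include_iq = cfg$model$include_iq,
                         group_column = subgroup_column)
  masks <- list()
  smoothness <- list()
  for (h in hemis) {
    fits_h <- lapply(smoothed[[h]], function(Y) fit_ols(Y, design))
    smoothness[[h]] <- lapply(fits_h, estimate_smoothness,
                              mesh = study$meshes[[h]])
  }
  for (alpha in cfg$inference$cluster_alphas) {
    lab <- threshold_label(alpha)
    masks[[lab]] <- lapply(features, function(f) {
      search <- sum(vapply(hemis, function(h) {
        smoothness[[h]][[f]]$total_resels
      }, numeric(1)))
      per_h <- lapply(hemis, function(h) {
        fit <- fit_ols(smoothed[[h]][[f]], design)
        significant_mask(contrast_t(fit, "group"), study$meshes[[h]],
                         smoothness[[h]][[f]], cluster_alpha = alpha,
                         forming_p = cfg$inference$forming_p,
                         search_resels = search)
      })
      stats::setNames(per_h, hemis)
    }) |> stats::setNames(features)
  }
  structure(list(config = cfg, cohort = sub, meshes = study$meshes,
                 masks = masks, subgroup_column = subgroup_column),
            class = "result_bundle")
}

#' Write a result bundle to disk
#'
#' Emits the cohort table, per-threshold cluster tables and signed masks
#' (curv format), the overlap/decomposition reports, the global
#' statistics, the effective configuration, and a manifest listing every
#' output file with its MD5 checksum.
#'
#' @param bundle a `result_bundle`.
#' @param outdir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisible character vector of written file paths.
#' @export
write_reports <- function(bundle, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force) {
    stop("output directory ", outdir,
         " is not empty; use force = TRUE to overwrite")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(rel) {
    written <<- c(written, rel)
    file.path(outdir, rel)
  }
  write_cohort(bundle$cohort, put("cohort.csv"))
  cfg_path <- put("config.yaml")
  yaml::write_yaml(bundle$config, cfg_path)

  if (!is.null(bundle$masks)) {
    for (lab in names(bundle$masks)) {
      safe <- gsub("[^0-9A-Za-z.]+", "_", lab)
      for (f in names(bundle$masks[[lab]])) {
        cl_rows <- list()
        for (h in names(bundle$masks[[lab]][[f]])) {
          m <- bundle$masks[[lab]][[f]][[h]]
          write_vertex_field(as.numeric(m),
                             put(sprintf("mask_%s_%s_%s.curv", f, h, safe)))
          cl <- attr(m, "clusters")
          if (!is.null(cl) && nrow(cl)) {
            cl$hemisphere <- h
            cl_rows[[h]] <- cl
          }
        }
        if (length(cl_rows)) {
          utils::write.csv(do.call(rbind, cl_rows),
                           put(sprintf("clusters_%s_%s.csv", f, safe)),
                           row.names = FALSE)
        }
      }
    }
  }
  if (!is.null(bundle$overlap_tables) ||
      !is.null(bundle$decomposition_tables)) {
    render_tables(bundle$overlap_tables, bundle$decomposition_tables,
                  outdir = outdir)
    written <- c(written, "overlap_tables.csv", "decomposition_tables.csv",
                 "tables_report.txt")
  }
  if (!is.null(bundle$global_stats)) {
    utils::write.csv(bundle$global_stats$group_tests,
                     put("global_group_tests.csv"), row.names = FALSE)
    utils::write.csv(bundle$global_stats$iq_correlations,
                     put("global_iq_correlations.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$null_overlap)) {
    no <- bundle$null_overlap
    utils::write.csv(
      data.frame(n_sims = no$n_sims, alpha = no$alpha,
                 observed_overlap_pct = no$observed_overlap_pct,
                 null_mean_pct = no$null_mean_pct, p_value = no$p_value),
      put("null_overlap.csv"), row.names = FALSE)
  }

  existing <- file.path(outdir, written)
  sums <- tools::md5sum(existing)
  manifest <- data.frame(file = written, md5 = unname(sums))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(c(written, "manifest.csv"))
}
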