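## Spatial overlap of thickness/area difference maps and the decomposition
## of volume differences into thickness- and area-driven components.
## Percentages are computed over the union of significantly different
## vertices (the "Total (100)" convention) and rounded half-up to two
## decimals.

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

as_mask_list <- function(mask) {
  if (is.list(mask)) lapply(mask, field_values)
  else list(combined = field_values(mask))
}

check_same_shape <- function(a, b, what) {
  if (!identical(names(a), names(b))) {
    stop("shape error: ", what, " masks cover different hemispheres")
  }
  for (h in names(a)) {
    if (length(a[[h]]) != length(b[[h]])) {
      stop("shape error: ", what, " masks differ in length for ", h)
    }
  }
}

#' Classify significant vertices as CT-only, SA-only or both
#'
#' A vertex in either signed mask is counted `ct_only` if only the
#' thickness mask is nonzero there, `sa_only` if only the area mask is,
#' and `both` if the two difference patterns overlap — regardless of
#' sign. Percentages are relative to the union of significant vertices.
#'
#' @param ct_mask,sa_mask signed masks (`{-1, 0, 1}` vectors) on the same
#'   template, or named lists of per-hemisphere masks (e.g.
#'   `list(left = ..., right = ...)`).
#' @param threshold_label optional label (e.g. `"p<0.05"`) carried into
#'   reports.
#' @return an `overlap_table` data.frame with columns `hemisphere`,
#'   `measure` (`ct_only`, `sa_only`, `both`, `total`), `count`, `pct`.
#' @export
classify_overlap <- function(ct_mask, sa_mask, threshold_label = "") {
  ct <- as_mask_list(ct_mask)
  sa <- as_mask_list(sa_mask)
  check_same_shape(ct, sa, "CT/SA")
  counts <- lapply(names(ct), function(h) {
    a <- ct[[h]] != 0; b <- sa[[h]] != 0
    c(ct_only = sum(a & !b), sa_only = sum(b & !a), both = sum(a & b))
  })
  names(counts) <- names(ct)
  overlap_table_from_counts(counts, threshold_label)
}

#' Build an overlap table from raw vertex counts
#'
#' The arithmetic core of [classify_overlap()], usable directly on
#' published count tables: takes `ct_only` / `sa_only` / `both` counts per
#' hemisphere, adds an across-hemispheres column when more than one
#' hemisphere is present, and computes percentages over the union total.
#'
#' @param counts named list, one element per hemisphere, each a named
#'   numeric vector with entries `ct_only`, `sa_only`, `both`.
#' @param threshold_label optional label carried into reports.
#' @return an `overlap_table` data.frame.
#' @examples
#' overlap_table_from_counts(list(
#'   left = c(ct_only = 10173, sa_only = 67029, both = 14951),
#'   right = c(ct_only = 12980, sa_only = 61442, both = 21293)))
#' @export
overlap_table_from_counts <- function(counts, threshold_label = "") {
  if (!is.list(counts)) counts <- list(combined = counts)
  for (ct in counts) {
    if (!all(c("ct_only", "sa_only", "both") %in% names(ct))) {
      stop("each count vector needs ct_only, sa_only and both entries")
    }
    if (any(ct < 0)) stop("counts must be non-negative")
  }
  if (length(counts) > 1L) {
    counts$across <- Reduce(`+`, counts[names(counts) != "across"])
  }
  rows <- lapply(names(counts), function(h) {
    ct <- counts[[h]][c("ct_only", "sa_only", "both")]
    total <- sum(ct)
    pct <- if (total > 0) round_half_up(100 * ct / total) else rep(0, 3)
    data.frame(hemisphere = h,
               measure = c(names(ct), "total"),
               count = c(unname(ct), total),
               pct = c(unname(pct), if (total > 0) 100 else 0))
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold_label") <- threshold_label
  class(out) <- c("overlap_table", "data.frame")
  out
}

#' Chi-square goodness-of-fit against equal category counts
#'
#' Tests the null hypothesis that significant vertices are equally
#' distributed over the categories (e.g. CT-only / SA-only / both), via
#' `sum((O - E)^2 / E)` with `E = sum(O) / k` and `df = k - 1`.
#'
#' @param counts non-negative category counts, not all zero.
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' chi2_equal_distribution(c(50, 25, 25))  # statistic 12.5, df 2
#' @export
chi2_equal_distribution <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero")
  k <- length(counts)
  expected <- sum(counts) / k
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, df = k - 1L,
       p = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

#' Simulation null for the CT/SA overlap percentage
#'
#' Tests whether an observed overlap percentage is compatible with two
#' spatially independent difference patterns: each simulation draws two
#' independent vertex-wise random statistic maps, thresholds them
#' two-tailed at `alpha`, and records
#' `100 * |both significant| / |either significant|`. The empirical p uses
#' the add-one estimator `(1 + #{null >= observed}) / (n_sims + 1)`, so it
#' is never zero. For independent maps the expected overlap is
#' `alpha^2 / (2 alpha - alpha^2)` (2.564% at alpha = 0.05).
#'
#' @param n_vertices vertices per map.
#' @param alpha vertex-level two-tailed threshold.
#' @param n_sims number of simulated map pairs.
#' @param seed integer seed.
#' @param observed_overlap_pct observed overlap percentage in `[0, 100]`.
#' @return a `null_overlap_result` list: `n_sims`, `alpha`,
#'   `observed_overlap_pct`, `null_overlap_pcts`, `null_mean_pct`,
#'   `p_value`.
#' @export
simulate_overlap_null <- function(n_vertices, alpha = 0.05, n_sims = 5000,
                                  seed = 1, observed_overlap_pct) {
  stopifnot(n_sims >= 1, alpha > 0, alpha <= 1, n_vertices >= 1)
  if (observed_overlap_pct < 0 || observed_overlap_pct > 100) {
    stop("observed_overlap_pct must be in [0, 100]")
  }
  thr <- stats::qnorm(1 - alpha / 2)
  null_pcts <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
    s1 <- abs(stats::rnorm(n_vertices)) > thr
    s2 <- abs(stats::rnorm(n_vertices)) > thr
    either <- sum(s1 | s2)
    if (either == 0) 0 else 100 * sum(s1 & s2) / either
  }, numeric(1)))
  structure(list(
    n_sims = n_sims, alpha = alpha,
    observed_overlap_pct = observed_overlap_pct,
    null_overlap_pcts = null_pcts,
    null_mean_pct = mean(null_pcts),
    p_value = (1 + sum(null_pcts >= observed_overlap_pct)) / (n_sims + 1)
  ), class = "null_overlap_result")
}

#' Decompose volume differences into thickness/area contributions
#'
#' Restricts to vertices with a significant volume difference, splits
#' them by direction (case < control vs case > control), and counts how
#' many co-occur with a significant thickness difference only, an area
#' difference only, both, or neither (sign of the CT/SA masks ignored for
#' membership). `cv_explained = ct_only + sa_only + ct_and_sa` and
#' `cv_explained + cv_unexplained = cv_total`.
#'
#' @param cv_mask,ct_mask,sa_mask signed masks or per-hemisphere lists
#'   (as in [classify_overlap()]).
#' @param threshold_label optional label carried into reports.
#' @return a `decomposition_table` data.frame with columns `direction`
#'   (`case_lt_control`, `case_gt_control`), `hemisphere`, `measure`,
#'   `count`, `pct` (percentages relative to that direction's `cv_total`).
#' @export
decompose_cv <- function(cv_mask, ct_mask, sa_mask, threshold_label = "") {
  cv <- as_mask_list(cv_mask)
  ct <- as_mask_list(ct_mask)
  sa <- as_mask_list(sa_mask)
  check_same_shape(cv, ct, "CV/CT")
  check_same_shape(cv, sa, "CV/SA")
  dirs <- c(case_lt_control = -1, case_gt_control = 1)
  counts <- lapply(names(dirs), function(dn) {
    s <- dirs[[dn]]
    out <- lapply(names(cv), function(h) {
      in_cv <- cv[[h]] == s
      a <- ct[[h]] != 0; b <- sa[[h]] != 0
      c(cv_total = sum(in_cv),
        ct_only = sum(in_cv & a & !b),
        sa_only = sum(in_cv & b & !a),
        ct_and_sa = sum(in_cv & a & b))
    })
    names(out) <- names(cv)
    out
  })
  names(counts) <- names(dirs)
  decomposition_table_from_counts(counts, threshold_label)
}

#' Build a decomposition table from raw vertex counts
#'
#' Arithmetic core of [decompose_cv()], usable directly on published
#' count tables.
#'
#' @param counts nested named list: per direction
#'   (`case_lt_control`, `case_gt_control`), per hemisphere, a named
#'   vector with `cv_total`, `ct_only`, `sa_only`, `ct_and_sa`.
#' @param threshold_label optional label.
#' @return a `decomposition_table` data.frame.
#' @export
decomposition_table_from_counts <- function(counts, threshold_label = "") {
  rows <- list()
  for (dn in names(counts)) {
    hemis <- counts[[dn]]
    if (!is.list(hemis)) hemis <- list(combined = hemis)
    if (length(hemis) > 1L) {
      hemis$across <- Reduce(`+`, hemis[names(hemis) != "across"])
    }
    for (h in names(hemis)) {
      ct <- hemis[[h]]
      need <- c("cv_total", "ct_only", "sa_only", "ct_and_sa")
      if (!all(need %in% names(ct))) {
        stop("each count vector needs ", paste(need, collapse = ", "))
      }
      if (any(ct < 0)) stop("counts must be non-negative")
      explained <- ct[["ct_only"]] + ct[["sa_only"]] + ct[["ct_and_sa"]]
      unexplained <- ct[["cv_total"]] - explained
      if (unexplained < 0) {
        stop("explained counts exceed cv_total for ", dn, "/", h)
      }
      vals <- c(cv_total = ct[["cv_total"]], ct_only = ct[["ct_only"]],
                sa_only = ct[["sa_only"]], ct_and_sa = ct[["ct_and_sa"]],
                cv_explained = explained, cv_unexplained = unexplained)
      tot <- ct[["cv_total"]]
      pct <- if (tot > 0) round_half_up(100 * vals / tot) else rep(0, 6)
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dn, hemisphere = h, measure = names(vals),
        count = unname(vals), pct = unname(pct))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold_label") <- threshold_label
  class(out) <- c("decomposition_table", "data.frame")
  out
}

#' Render overlap and decomposition tables as text and CSV
#'
#' One block per cluster-significance threshold, cells formatted as
#' `count(pct)` with two-decimal percentages.
#'
#' @param overlap named list of `overlap_table`s keyed by threshold label.
#' @param decomp named list of `decomposition_table`s keyed likewise.
#' @param outdir optional directory; when given, writes
#'   `overlap_tables.csv`, `decomposition_tables.csv` and
#'   `tables_report.txt`.
#' @return invisible list with `text` (character lines), `overlap_csv`
#'   and `decomp_csv` data.frames.
#' @export
render_tables <- function(overlap = list(), decomp = list(),
                          outdir = NULL) {
  if (!length(overlap) && !length(decomp)) {
    stop("at least one table must be supplied")
  }
  fmt_cell <- function(count, pct) {
    if (count == 0 && pct == 0) "0(0)"
    else sprintf("%d(%.2f)", count, pct)
  }
  lines <- character()
  ov_rows <- list(); dc_rows <- list()
  for (lab in names(overlap)) {
    tb <- overlap[[lab]]
    tb$threshold <- lab
    ov_rows[[lab]] <- tb
    lines <- c(lines, paste0("Overlap ", lab), "")
    for (h in unique(tb$hemisphere)) {
      sub <- tb[tb$hemisphere == h, ]
      lines <- c(lines, paste0("  [", h, "]"))
      for (i in seq_len(nrow(sub))) {
        lines <- c(lines, sprintf("    %-10s %s", sub$measure[i],
                                  fmt_cell(sub$count[i], sub$pct[i])))
      }
    }
    lines <- c(lines, "")
  }
  for (lab in names(decomp)) {
    tb <- decomp[[lab]]
    tb$threshold <- lab
    dc_rows[[lab]] <- tb
    lines <- c(lines, paste0("CV decomposition ", lab), "")
    for (dn in unique(tb$direction)) {
      for (h in unique(tb$hemisphere[tb$direction == dn])) {
        sub <- tb[tb$direction == dn & tb$hemisphere == h, ]
        lines <- c(lines, sprintf("  [%s, %s]", dn, h))
        for (i in seq_len(nrow(sub))) {
          lines <- c(lines, sprintf("    %-14s %s", sub$measure[i],
                                    fmt_cell(sub$count[i], sub$pct[i])))
        }
      }
    }
    lines <- c(lines, "")
  }
  ov_csv <- if (length(ov_rows)) do.call(rbind, ov_rows) else NULL
  dc_csv <- if (length(dc_rows)) do.call(rbind, dc_rows) else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(ov_csv)) {
      utils::write.csv(ov_csv, file.path(outdir, "overlap_tables.csv"),
                       row.names = FALSE)
    }
    if (!is.null(dc_csv)) {
      utils::write.csv(dc_csv, file.path(outdir, "decomposition_tables.csv"),
                       row.names = FALSE)
    }
    writeLines(lines, file.path(outdir, "tables_report.txt"))
  }
  invisible(list(text = lines, overlap_csv = ov_csv, decomp_csv = dc_csv))
}
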