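#' Fit per-vertex ordinary least squares
#'
#' One QR decomposition of the design is shared across all vertices, so
#' the whole subjects-by-vertices matrix is fit in a single pass.
#'
#' @param Y n x V measure matrix (or `vertex_field` values bound as
#'   columns).
#' @param X a `design_matrix` from [build_design()] or a plain numeric
#'   matrix.
#' @return a `glm_fit`: `betas` (p x V), `residuals` (n x V), `sigma2`
#'   (length V), `df_resid`, `XtX_inv`, and the design matrix `X`.
#' @export
fit_ols <- function(Y, X) {
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(Xm)) stop("rows of Y must match rows of the design")
  n <- nrow(Xm); p <- ncol(Xm)
  if (n <= p) stop("insufficient residual degrees of freedom (n = ", n,
                   ", p = ", p, ")")
  qrX <- qr(Xm)
  betas <- qr.coef(qrX, Y)
  res <- Y - Xm %*% betas
  df <- n - p
  sigma2 <- colSums(res^2) / df
  structure(list(betas = betas, residuals = res, sigma2 = sigma2,
                 df_resid = df, XtX_inv = chol2inv(chol(crossprod(Xm))),
                 X = Xm,
                 design = if (inherits(X, "design_matrix")) X else NULL),
            class = "glm_fit")
}

#' Per-vertex statistic map
#'
#' @param statistic numeric vector of per-vertex t or F values.
#' @param kind `"t"` or `"F"`.
#' @param df degrees of freedom: scalar for t, `c(df1, df2)` for F.
#' @param contrast label describing the tested effect.
#' @return a `stat_map` object.
#' @export
stat_map <- function(statistic, kind = c("t", "F"), df, contrast = "") {
  kind <- match.arg(kind)
  statistic <- as.numeric(statistic)
  if (any(!is.finite(statistic))) stop("stat map contains non-finite values")
  if (kind == "F" && any(statistic < 0)) stop("F statistics must be >= 0")
  structure(list(statistic = statistic, kind = kind, df = df,
                 contrast = contrast), class = "stat_map")
}

#' t map for a coefficient contrast
#'
#' Computes `t = c'beta / sqrt(sigma2 * c' (X'X)^-1 c)` per vertex with
#' `n - p` degrees of freedom.
#'
#' @param fit a `glm_fit`.
#' @param contrast numeric weight vector of length p, or the name of a
#'   single design column.
#' @return a `stat_map` of kind `"t"`.
#' @export
contrast_t <- function(fit, contrast) {
  p <- ncol(fit$X)
  label <- ""
  if (is.character(contrast)) {
    label <- contrast
    idx <- match(contrast, colnames(fit$X))
    if (is.na(idx)) stop("no design column named '", contrast, "'")
    cvec <- numeric(p); cvec[idx] <- 1
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != p) stop("contrast must have length ", p)
  }
  if (all(cvec == 0)) stop("contrast must be nonzero")
  num <- as.numeric(crossprod(cvec, fit$betas))
  se <- sqrt(fit$sigma2 * as.numeric(crossprod(cvec, fit$XtX_inv %*% cvec)))
  stat_map(num / se, "t", fit$df_resid, label)
}

#' Nested-model F map
#'
#' `F = ((RSS_r - RSS_f) / q) / (RSS_f / df_f)` per vertex, where `q` is
#' the number of extra columns in the full model.
#'
#' @param fit_reduced,fit_full `glm_fit` objects for the same response
#'   matrix; the reduced design's columns must be a subset of the full
#'   design's.
#' @return a `stat_map` of kind `"F"` with `df = c(q, df_full)`.
#' @export
nested_f <- function(fit_reduced, fit_full) {
  if (nrow(fit_reduced$X) != nrow(fit_full$X)) {
    stop("models were fit to different numbers of subjects")
  }
  nm_r <- colnames(fit_reduced$X); nm_f <- colnames(fit_full$X)
  if (!all(nm_r %in% nm_f)) {
    stop("designs are not nested: reduced columns ",
         paste(setdiff(nm_r, nm_f), collapse = ", "),
         " absent from the full model")
  }
  q <- ncol(fit_full$X) - ncol(fit_reduced$X)
  if (q == 0) stop("designs are identical (q = 0); nothing to test")
  rss_r <- fit_reduced$sigma2 * fit_reduced$df_resid
  rss_f <- fit_full$sigma2 * fit_full$df_resid
  fstat <- pmax(0, (rss_r - rss_f) / q) / (rss_f / fit_full$df_resid)
  stat_map(fstat, "F", c(q, fit_full$df_resid),
           paste0("nested q=", q))
}

#' Step-up age-model selection
#'
#' Compares the linear age model to the quadratic by a vertex-wise nested
#' F test with RFT cluster correction; if any cluster is significant, the
#' quadratic model is compared to the cubic in the same way. The globally
#' adopted polynomial order is the most complex one whose addition
#' produced at least one significant cluster.
#'
#' @param Y n x V measure matrix on `mesh`.
#' @param cohort covariate table covering the rows of `Y`.
#' @param mesh the template `surf_mesh`.
#' @param cluster_alpha cluster-level significance for each step.
#' @param forming_p vertex-level cluster-forming threshold.
#' @param with_interactions include age-by-group interactions at each
#'   order.
#' @param ... further arguments to [build_design()].
#' @return list with `adopted_order`, and per-step `clusters`
#'   (`cluster_set` objects) and F `stat_map`s.
#' @export
stepup_select <- function(Y, cohort, mesh, cluster_alpha = 0.05,
                          forming_p = 0.001, with_interactions = TRUE,
                          ...) {
  fits <- lapply(1:3, function(k) {
    fit_ols(Y, build_design(cohort, age_order = k,
                            with_interactions = with_interactions, ...))
  })
  run_step <- function(red, full) {
    fmap <- nested_f(fits[[red]], fits[[full]])
    sm <- estimate_smoothness(fits[[full]], mesh)
    cl <- extract_clusters(fmap, mesh, forming_p, tail = "positive")
    cl <- cluster_pvalues(cl, sm, two_tailed = FALSE)
    list(f_map = fmap, clusters = cl,
         significant = any(cl$clusters$p_cluster <= cluster_alpha))
  }
  step1 <- run_step(1, 2)
  adopted <- 1L
  step2 <- NULL
  if (step1$significant) {
    adopted <- 2L
    step2 <- run_step(2, 3)
    if (step2$significant) adopted <- 3L
  }
  list(adopted_order = adopted,
       step1 = step1, step2 = step2)
}

#' Group comparisons and correlations of global brain measures
#'
#' Two-sample pooled-variance t tests (df `n1 + n2 - 2`) on each global
#' measure, and Pearson correlations of IQ with the global measures
#' overall and within each group.
#'
#' @param cohort a `cohort_table` with `iq`, `total_sa`, `mean_ct`,
#'   `total_cv` columns.
#' @return list of two data.frames: `group_tests` (measure, t, df, p) and
#'   `iq_correlations` (measure, subset, r, p).
#' @export
global_stats <- function(cohort) {
  measures <- intersect(c("age", "iq", "total_cv", "mean_ct", "total_sa"),
                        names(cohort))
  case <- cohort[cohort$group == "case", , drop = FALSE]
  ctrl <- cohort[cohort$group == "control", , drop = FALSE]
  tests <- do.call(rbind, lapply(measures, function(m) {
    tt <- stats::t.test(case[[m]], ctrl[[m]], var.equal = TRUE)
    data.frame(measure = m, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  cor_targets <- intersect(c("total_cv", "total_sa", "mean_ct"),
                           names(cohort))
  subsets <- list(all = cohort, case = case, control = ctrl)
  cors <- do.call(rbind, unlist(lapply(cor_targets, function(m) {
    lapply(names(subsets), function(s) {
      d <- subsets[[s]]
      if (stats::sd(d[[m]]) == 0 || stats::sd(d$iq) == 0) {
        stop("correlation undefined: constant column '", m, "'")
      }
      ct <- stats::cor.test(d$iq, d[[m]])
      data.frame(measure = m, subset = s, r = unname(ct$estimate),
                 p = ct$p.value)
    })
  }), recursive = FALSE))
  list(group_tests = tests, iq_correlations = cors)
}
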