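make_coh <- function(n = 30, seed = 1) {
  coh <- generate_cohort(n, n, seed = seed)
  # guarantee variation in the relatedness indicator at small n
  coh$related <- rep(c("yes", "no", "no", "no"), length.out = nrow(coh))
  coh
}

test_that("design matrix has the documented columns and centering", {
  coh <- generate_cohort(seed = 1)
  X2 <- build_design(coh, age_order = 2, with_interactions = TRUE)
  expect_identical(
    colnames(X2$X),
    c("intercept", "site", "group", "age", "age2", "age_x_group",
      "age2_x_group", "sex", "iq", "related", "total_sa"))
  expect_equal(ncol(X2$X), 11)
  X1 <- build_design(coh, age_order = 1, with_interactions = FALSE)
  expect_true(all(colnames(X1$X) %in% colnames(X2$X)))
  # continuous covariates centered across the combined sample
  for (cl in c("age", "age2", "iq", "total_sa")) {
    expect_lt(abs(mean(X2$X[, cl])), 1e-12)
  }
  # IQ toggle drops exactly that column
  expect_false("iq" %in% colnames(build_design(coh, include_iq = FALSE)$X))
  # a constant factor column is caught as rank deficiency
  coh2 <- coh
  coh2$site <- "A"
  expect_error(build_design(coh2), "collinear.*site")
})

test_that("OLS matches the normal-equations oracle and is exact on noiseless data", {
  set.seed(21)
  coh <- make_coh(15)
  X <- build_design(coh, age_order = 1, with_interactions = FALSE)
  p <- ncol(X$X)
  b <- matrix(rnorm(p * 10), p, 10)
  Y0 <- X$X %*% b
  fit0 <- fit_ols(Y0, X)
  expect_equal(unname(fit0$betas), unname(b), tolerance = 1e-10)
  Y <- Y0 + matrix(rnorm(nrow(Y0) * 10), nrow(Y0))
  fit <- fit_ols(Y, X)
  oracle <- solve(crossprod(X$X), t(X$X) %*% Y)
  expect_equal(unname(fit$betas), unname(oracle), tolerance = 1e-8)
  # residual orthogonality invariant
  expect_lt(max(abs(crossprod(X$X, fit$residuals))), 1e-8 * max(abs(Y)))
  expect_error(fit_ols(Y[1:5, ], X$X[1:5, ]), "insufficient")
})

test_that("residual variance estimate is unbiased on pure noise", {
  set.seed(31)
  coh <- make_coh(15)
  X <- build_design(coh, age_order = 2)
  Y <- matrix(rnorm(nrow(X$X) * 1000), nrow(X$X), 1000)
  fit <- fit_ols(Y, X)
  expect_equal(mean(fit$sigma2), 1, tolerance = 0.1)
})

test_that("contrast t maps are antisymmetric in group coding and calibrated", {
  set.seed(41)
  coh <- make_coh(25)
  X <- build_design(coh, age_order = 2)
  Y <- matrix(rnorm(nrow(X$X) * 5000), nrow(X$X), 5000)
  fit <- fit_ols(Y, X)
  tmap <- contrast_t(fit, "group")
  expect_equal(tmap$df, nrow(X$X) - ncol(X$X))
  # empirical type-I error at alpha = 0.05 across null vertices
  crit <- qt(0.975, tmap$df)
  expect_lt(abs(mean(abs(tmap$statistic) > crit) - 0.05), 0.01)
  # flipping the group indicator flips every t exactly
  Xf <- X
  Xf$X[, "group"] <- 1 - Xf$X[, "group"]
  tf <- contrast_t(fit_ols(Y, Xf$X), colnames(X$X) == "group")
  expect_equal(tf$statistic, -tmap$statistic, tolerance = 1e-10)
  expect_error(contrast_t(fit, rep(0, ncol(X$X))), "nonzero")
})

test_that("nested F agrees with the anova oracle and equals t^2 for one column", {
  set.seed(51)
  coh <- make_coh(20)
  Xr <- build_design(coh, age_order = 1, with_interactions = FALSE)
  Xf <- build_design(coh, age_order = 2, with_interactions = FALSE)
  n <- nrow(Xr$X)
  Y <- matrix(rnorm(n * 20), n, 20)
  fr <- fit_ols(Y, Xr); ff <- fit_ols(Y, Xf)
  fmap <- nested_f(fr, ff)
  expect_equal(fmap$df, c(1, n - ncol(Xf$X)))
  # independent oracle: R's anova() on each vertex
  for (v in c(1, 7, 20)) {
    a <- anova(lm(Y[, v] ~ Xr$X - 1), lm(Y[, v] ~ Xf$X - 1))
    expect_equal(fmap$statistic[v], a$F[2], tolerance = 1e-8)
  }
  # t^2 = F for single-column nesting
  tmap <- contrast_t(ff, "age2")
  expect_equal(fmap$statistic, tmap$statistic^2, tolerance = 1e-10)
  # F is invariant to rescaling Y
  fmap10 <- nested_f(fit_ols(10 * Y, Xr), fit_ols(10 * Y, Xf))
  expect_equal(fmap10$statistic, fmap$statistic, tolerance = 1e-10)
  expect_error(nested_f(fr, fr), "identical")
  expect_error(nested_f(ff, fr), "not nested")
})

test_that("centering changes coefficients but not fitted values", {
  set.seed(61)
  coh <- make_coh(20)
  X <- build_design(coh, age_order = 2)
  n <- nrow(X$X)
  Y <- matrix(rnorm(n * 5), n, 5)
  # uncentered variant of the same column space
  age <- coh$age
  Xu <- cbind(1, X$X[, "site"], X$X[, "group"], age, age^2,
              age * X$X[, "group"], age^2 * X$X[, "group"],
              X$X[, "sex"], coh$iq, X$X[, "related"], coh$total_sa)
  fit_c <- fit_ols(Y, X)
  fit_u <- fit_ols(Y, Xu)
  expect_equal(fit_u$residuals, fit_c$residuals, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(unname(fit_u$betas), unname(fit_c$betas))))
})

test_that("step-up selection adopts the generating polynomial order", {
  m <- make_icosphere(2)
  coh <- generate_cohort(30, 30, seed = 71,
                         mean_ct_case = c(2.7, 0.02),
                         mean_ct_control = c(2.7, 0.02))
  cage <- coh$age - mean(coh$age)
  # spatially smooth noise: cluster-level RFT assumes smooth fields
  base <- function(noise_sd = 0.05) {
    smooth_field(m, matrix(rnorm(nrow(coh) * m$V, sd = noise_sd),
                           nrow(coh), m$V), 15)
  }
  set.seed(71)
  # a 1% cluster alpha keeps chance adoption of a higher order rare
  # while the planted trends are strong enough to stay detectable
  lin <- outer(0.02 * cage, rep(1, m$V)) + base()
  sel_lin <- stepup_select(lin, coh, m, cluster_alpha = 0.01)
  expect_equal(sel_lin$adopted_order, 1)
  quad <- outer(0.02 * cage - 0.004 * cage^2, rep(1, m$V)) + base()
  expect_equal(stepup_select(quad, coh, m,
                             cluster_alpha = 0.01)$adopted_order, 2)
  cub <- outer(0.004 * cage^2 + 0.002 * cage^3, rep(1, m$V)) + base()
  expect_equal(stepup_select(cub, coh, m,
                             cluster_alpha = 0.01)$adopted_order, 3)
})

test_that("global statistics report pooled df and exact correlations", {
  coh <- generate_cohort(seed = 1)
  gs <- global_stats(coh)
  expect_true(all(gs$group_tests$df == 117))
  # identical groups give t = 0
  coh2 <- coh
  coh2$iq <- rep(coh$iq[1:10], length.out = nrow(coh))
  coh2$iq[coh2$group == "case"] <- coh2$iq[coh2$group == "control"][1:62]
  eq <- data.frame(group = rep(c("case", "control"), each = 4),
                   iq = rep(c(90, 100, 110, 120), 2),
                   age = rep(c(10, 15, 20, 25), 2),
                   total_sa = rep(c(0.2, 0.21, 0.22, 0.23), 2))
  eq$mean_ct <- 2 + 0.01 * eq$iq   # r = 1 with IQ by construction
  eq$total_cv <- eq$mean_ct * eq$total_sa
  gs2 <- global_stats(eq)
  expect_equal(gs2$group_tests$t[gs2$group_tests$measure == "iq"], 0)
  r_ct <- gs2$iq_correlations
  expect_equal(r_ct$r[r_ct$measure == "mean_ct" & r_ct$subset == "all"], 1)
  const <- eq; const$mean_ct <- 2.5
  expect_error(global_stats(const), "constant")
})
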