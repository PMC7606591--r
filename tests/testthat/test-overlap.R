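test_that("overlap classification matches the exhaustive per-vertex tally", {
  set.seed(141)
  for (rep in 1:10) {
    ct <- sample(c(-1, 0, 1), 10, replace = TRUE)
    sa <- sample(c(-1, 0, 1), 10, replace = TRUE)
    tab <- classify_overlap(ct, sa)
    oracle <- overlap_tally_oracle(ct, sa)
    for (ms in names(oracle)) {
      expect_equal(tab$count[tab$measure == ms], unname(oracle[ms]))
    }
    # counting identity: categories sum to the union total
    expect_equal(sum(tab$count[tab$measure != "total"]),
                 tab$count[tab$measure == "total"])
  }
})

test_that("disjoint and mismatched masks are handled", {
  ct <- c(1, 1, 0, 0, 0, -1)
  sa <- c(0, 0, 1, -1, 0, 0)
  tab <- classify_overlap(ct, sa)
  expect_equal(tab$count[tab$measure == "both"], 0)
  expect_equal(tab$count[tab$measure == "total"], 5)
  expect_error(classify_overlap(ct, sa[1:3]), "shape error")
  expect_error(classify_overlap(list(left = ct), list(right = sa)),
               "shape error")
})

test_that("per-hemisphere tables gain an across-hemispheres column", {
  tab <- overlap_table_from_counts(list(
    left = c(ct_only = 1, sa_only = 2, both = 1),
    right = c(ct_only = 3, sa_only = 0, both = 1)))
  across <- tab[tab$hemisphere == "across", ]
  expect_equal(across$count[across$measure == "ct_only"], 4)
  expect_equal(across$count[across$measure == "total"], 8)
  expect_equal(across$pct[across$measure == "ct_only"], 50)
})

test_that("chi-square goodness-of-fit follows the direct formula", {
  eq <- chi2_equal_distribution(c(100, 100, 100))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  r <- chi2_equal_distribution(c(50, 25, 25))
  expect_equal(r$statistic, 12.5)
  expect_equal(r$df, 2L)
  expect_equal(r$p, pchisq(12.5, 2, lower.tail = FALSE))
  # invariant under permutation of categories
  expect_equal(chi2_equal_distribution(c(25, 50, 25))$statistic, 12.5)
  expect_error(chi2_equal_distribution(c(0, 0, 0)), "zero")
  expect_error(chi2_equal_distribution(c(-1, 2)), "non-negative")
})

test_that("simulation null saturates at alpha = 1 and uses the add-one p", {
  r <- simulate_overlap_null(100, alpha = 1, n_sims = 20, seed = 1,
                             observed_overlap_pct = 50)
  expect_true(all(r$null_overlap_pcts == 100))
  expect_equal(r$p_value, 1)
  r2 <- simulate_overlap_null(2000, alpha = 0.05, n_sims = 99, seed = 2,
                              observed_overlap_pct = 100)
  expect_equal(r2$p_value, 1 / 100)   # nothing reaches 100%
  expect_true(r2$p_value > 0)
  expect_error(simulate_overlap_null(100, 0.05, 10, 1, 101), "\\[0, 100\\]")
})

test_that("simulation null mean approaches the independence value", {
  # alpha^2 / (2 alpha - alpha^2) at several thresholds
  for (alpha in c(0.01, 0.05, 0.2)) {
    expected <- 100 * alpha^2 / (2 * alpha - alpha^2)
    r <- simulate_overlap_null(50000, alpha = alpha, n_sims = 40,
                               seed = 3, observed_overlap_pct = 50)
    expect_equal(r$null_mean_pct, expected, tolerance = 0.15)
  }
})

test_that("volume decomposition matches the tally oracle and its identities", {
  set.seed(151)
  for (rep in 1:10) {
    cv <- sample(c(-1, 0, 1), 20, replace = TRUE)
    ct <- sample(c(-1, 0, 1), 20, replace = TRUE)
    sa <- sample(c(-1, 0, 1), 20, replace = TRUE)
    tab <- decompose_cv(cv, ct, sa)
    for (dn in c(case_lt_control = -1, case_gt_control = 1)) {
      dir_name <- names(which(c(case_lt_control = -1,
                                case_gt_control = 1) == dn))
      sub <- tab[tab$direction == dir_name, ]
      g <- function(ms) sub$count[sub$measure == ms]
      in_cv <- cv == dn
      expect_equal(g("cv_total"), sum(in_cv))
      expect_equal(g("ct_only"), sum(in_cv & ct != 0 & sa == 0))
      expect_equal(g("sa_only"), sum(in_cv & sa != 0 & ct == 0))
      expect_equal(g("ct_and_sa"), sum(in_cv & ct != 0 & sa != 0))
      expect_equal(g("cv_explained"),
                   g("ct_only") + g("sa_only") + g("ct_and_sa"))
      expect_equal(g("cv_explained") + g("cv_unexplained"), g("cv_total"))
    }
  }
  # empty CV mask renders as all-zero rows
  empty <- decompose_cv(rep(0, 5), c(1, 0, 0, 0, 0), rep(0, 5))
  expect_true(all(empty$count == 0))
  expect_true(all(empty$pct == 0))
})

test_that("rendered tables use count(pct) cells and are reproducible", {
  ov <- overlap_table_from_counts(list(
    left = c(ct_only = 3, sa_only = 5, both = 2)))
  dc <- decomposition_table_from_counts(list(
    case_lt_control = list(left = c(cv_total = 4, ct_only = 0,
                                    sa_only = 4, ct_and_sa = 0)),
    case_gt_control = list(left = c(cv_total = 0, ct_only = 0,
                                    sa_only = 0, ct_and_sa = 0))))
  out1 <- render_tables(list("p<0.05" = ov), list("p<0.05" = dc))
  out2 <- render_tables(list("p<0.05" = ov), list("p<0.05" = dc))
  expect_identical(out1$text, out2$text)
  expect_true(any(grepl("3(30.00)", out1$text, fixed = TRUE)))
  # zero-count cells print as 0(0)
  expect_true(any(grepl("0(0)", out1$text, fixed = TRUE)))
  expect_error(render_tables(), "at least one")
})
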