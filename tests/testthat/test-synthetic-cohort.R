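test_that("default cohort reproduces the intended marginals", {
  coh <- generate_cohort(seed = 1)
  expect_s3_class(coh, "cohort_table")
  expect_equal(sum(coh$group == "case"), 62)
  expect_equal(sum(coh$group == "control"), 57)
  expect_true(all(coh$age >= 6 & coh$age <= 31))
  expect_true(all(coh$total_sa > 0))
  expect_true(all(coh$iq >= 60))
  expect_true(all(coh$psychosis_prodromal[coh$group == "control"] == "n/a"))
  # same seed -> identical table; different seed -> different draws
  expect_identical(coh, generate_cohort(seed = 1))
  expect_false(identical(coh$age, generate_cohort(seed = 2)$age))
  expect_error(generate_cohort(n_case = 0), "non-empty")
})

test_that("group separation in total surface area has the intended power", {
  # at n = 200/group and d ~ 1.1 a two-sample t at alpha = 0.001 should
  # essentially always reject
  reject <- vapply(1:100, function(s) {
    coh <- generate_cohort(200, 200, seed = s)
    tt <- t.test(total_sa ~ group, coh, var.equal = TRUE)
    tt$p.value < 0.001
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("cohort CSV round-trips through read/write", {
  coh <- generate_cohort(n_case = 5, n_control = 5, seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, p)
  back <- read_cohort(p)
  expect_equal(back$age, coh$age)
  expect_identical(back$group, coh$group)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_cohort(bad), "missing columns")
})

test_that("volume is the exact thickness-area product when CV noise is off", {
  m <- make_icosphere(2)
  coh <- generate_cohort(8, 8, seed = 4)
  gm <- generate_measures(m, coh, seed = 4, cv_noise_sd = 0)
  expect_lt(max(abs(gm$cv / (gm$ct * gm$sa) - 1)), 1e-12)
  expect_true(all(gm$sa > 0))
  # deterministic under a fixed seed
  gm2 <- generate_measures(m, coh, seed = 4, cv_noise_sd = 0)
  expect_identical(gm$ct, gm2$ct)
  expect_error(
    generate_measures(m, coh, list(effect_spec("CT", m$V + 1, 2, 1))),
    "out of range")
})

test_that("planted effects shift group means by the stated amplitude", {
  m <- make_icosphere(3)
  coh <- generate_cohort(40, 40, seed = 9,
                         mean_ct_case = c(2.72, 0),
                         mean_ct_control = c(2.72, 0))
  ef <- effect_spec("CT", 10, 5, effect_size = 2, sign = 1)
  gm <- generate_measures(m, coh, list(ef), noise_fwhm_mm = 0, seed = 9)
  inside <- gm$truth$ct_effect_mask != 0
  expect_gt(sum(inside), 10)
  diff_in <- colMeans(gm$ct[coh$group == "case", inside]) -
    colMeans(gm$ct[coh$group == "control", inside])
  # planted amplitude is d * ct_noise_sd = 2 * 0.25 = 0.5 mm
  expect_equal(mean(diff_in), 0.5, tolerance = 0.1)
  expect_identical(sort(unique(gm$truth$ct_effect_mask)), c(0, 1))
  expect_true(all(gm$truth$sa_effect_mask == 0))
})

test_that("overlap scenarios hit the requested truth-mask overlap", {
  m <- make_icosphere(4)
  adj <- build_adjacency(m)
  jaccard <- function(specs) {
    a <- which(hop_distances(adj, specs[[1]]$seed_vertex) <=
                 specs[[1]]$radius_hops)
    b <- which(hop_distances(adj, specs[[2]]$seed_vertex) <=
                 specs[[2]]$radius_hops)
    length(intersect(a, b)) / length(union(a, b))
  }
  expect_equal(jaccard(plant_overlap_scenario(m, 0, seed = 2)), 0)
  expect_equal(jaccard(plant_overlap_scenario(m, 1, seed = 2)), 1)
  for (s in 1:5) {
    j <- jaccard(plant_overlap_scenario(m, 0.2, seed = s))
    # achievable fractions step by roughly one adjacency ring
    expect_lt(abs(j - 0.2), 0.06)
  }
  # a disk radius covering the whole mesh makes any partial overlap
  # unreachable
  expect_error(plant_overlap_scenario(make_icosphere(1), 0,
                                      radius_hops = 20),
               "unreachable")
})
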