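test_that("Mann-Whitney U statistic and exact p match enumeration", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(enumMannWhitneyP(c(1, 2, 3), c(4, 5, 6)), 0.1)

  a <- c(1, 2, 3, 4)
  mw2 <- suppressWarnings(mannWhitneyU(a, a))
  expect_equal(mw2$U, length(a)^2 / 2)
  expect_gt(mw2$p, 0.9)

  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(mannWhitneyU(x, y)$U + mannWhitneyU(y, x)$U,
                 length(x) * length(y))
    # p invariant under monotone transforms of the pooled data
    expect_equal(mannWhitneyU(exp(x), exp(y))$p, mannWhitneyU(x, y)$p)
  }
  expect_error(mannWhitneyU(numeric(0), 1:3), "nonempty")
})

test_that("normal approximation tracks enumeration within its documented envelope", {
  # documented tolerance: |approx - exact| <= 0.035 everywhere for
  # 4 <= n <= 6; relative error <= 10% where exact p >= 0.05
  set.seed(13)
  for (i in 1:40) {
    na <- sample(4:6, 1); nb <- sample(4:6, 1)
    x <- rnorm(na); y <- rnorm(nb, sample(c(0, 1, 2), 1))
    pe <- enumMannWhitneyP(x, y)
    pa <- mannWhitneyU(x, y)$p
    expect_lt(abs(pa - pe), 0.035)
    if (pe >= 0.05) expect_lt(abs(pa - pe) / pe, 0.10)
  }
})

test_that("Cohen's d uses the pooled SD and its large-sample CI", {
  x <- c(1, 2, 3, 4)
  cd <- cohensD(x, x)
  expect_equal(cd$d, 0)
  expect_equal(cd$magnitude, "negligible")

  cd2 <- cohensD(c(0, 0, 2, 2), c(1, 1, 3, 3))
  expect_equal(cd2$d, -sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(round(cd2$d, 3), -0.866)
  expect_equal(cd2$magnitude, "large")
  se <- sqrt(8 / 16 + cd2$d^2 / 12)
  expect_equal(cd2$ci, cd2$d + c(-1.96, 1.96) * se, tolerance = 1e-12)

  # invariant under a shared positive affine map
  set.seed(2)
  a <- rnorm(5); b <- rnorm(6, 1)
  expect_equal(cohensD(3 * a + 7, 3 * b + 7)$d, cohensD(a, b)$d,
               tolerance = 1e-12)
  expect_error(cohensD(1, c(1, 2)), "at least 2")
  expect_warning(inf <- cohensD(c(1, 1), c(2, 2)), "zero pooled SD")
  expect_true(is.infinite(inf$d))
})

test_that("percent reduction compares treated to control rates", {
  expect_equal(round(percentReduction(0.175, 0.257), 1), 31.9)
  expect_equal(round(percentReduction(0.153, 0.250), 1), 38.8)
  expect_equal(percentReduction(0.2, 0.2), 0)
  expect_error(percentReduction(0.1, 0), "nonzero")
})

test_that("group rate comparison filters by validity and signals insufficiency", {
  days <- c(0, 2, 4, 7, 9)
  ts <- makeCleanCohort(c(0.28, 0.30, 0.32, 0.29, 0.31,
                          0.10, 0.12, 0.11, 0.13, 0.09),
                        c(rep("Control", 5), rep("Treated", 5)), days)
  fits <- fitGrowth(ts)
  cmp <- compareGrowthRates(fits, "Treated", "Control")
  expect_equal(cmp$status, "ok")
  expect_lt(cmp$p, 0.05)
  expect_lt(cmp$d, 0)        # treated minus control
  expect_equal(cmp$n_a, 5)
  expect_gt(cmp$percent_reduction, 50)

  # identical groups: d = 0, p near 1
  ts2 <- makeCleanCohort(rep(c(0.2, 0.25, 0.3), 2),
                         rep(c("A", "B"), each = 3), days)
  cmp2 <- suppressWarnings(
    compareGrowthRates(fitGrowth(ts2), "A", "B"))
  expect_equal(cmp2$d, 0)
  expect_gt(cmp2$p, 0.9)

  # validity filtering can empty a group -> insufficient-data signal
  f <- as.data.frame(fits)
  f$valid[f$group == "Treated"] <- FALSE
  expect_equal(compareGrowthRates(S4Vectors::DataFrame(f), "Treated",
                                  "Control")$status,
               "insufficient_data")
})

test_that("interval comparisons carry medians, effect sizes and the diagonal marker", {
  days <- c(0, 3, 7, 10)
  treated <- makeCleanCohort(c(0.10, 0.11, 0.09), rep("T", 3), days)
  control <- makeCleanCohort(c(0.30, 0.31, 0.29), rep("C", 3), days)
  mt <- studyTGRMatrices(treated); mc <- studyTGRMatrices(control)

  all <- compareAllIntervals(mt, mc)
  expect_equal(nrow(all), intervalCount(4))
  ok <- all[all$status == "ok", ]
  expect_true(all(ok$d < 0))           # treated minus control, suppressed
  expect_true(all(ok$median_a < ok$median_b))

  # corrections attach only to diagonal (consecutive-day) intervals
  expect_true(all(is.na(all$p_bonferroni[!all$diagonal])))
  expect_true(all(!is.na(all$p_bonferroni[all$diagonal])))

  one <- compareInterval(mt, mc, 0, 7)
  expect_false(one$diagonal)
  expect_true(is.na(one$p_bonferroni))

  # a single animal in one group is insufficient
  single <- compareInterval(mt[1], mc, 0, 3)
  expect_equal(single$status, "insufficient_data")
})

test_that("diagonal corrections follow Bonferroni and Benjamini-Hochberg", {
  d1 <- data.frame(p = 0.01, diagonal = TRUE)
  c1 <- correctDiagonal(d1)
  expect_equal(c1$p_bonferroni, 0.01)
  expect_equal(c1$q_bh, 0.01)

  d3 <- data.frame(p = c(0.01, 0.04, 0.03), diagonal = TRUE)
  c3 <- correctDiagonal(d3)
  expect_equal(c3$p_bonferroni, c(0.03, 0.12, 0.09))
  # step-up BH with cummin from the largest rank:
  # sorted q = (.03, .045, .04) -> (.03, .04, .04)
  expect_equal(c3$q_bh, c(0.03, 0.04, 0.04))

  cAll1 <- correctDiagonal(data.frame(p = rep(1, 4), diagonal = TRUE))
  expect_equal(cAll1$p_bonferroni, rep(1, 4))
  expect_equal(cAll1$q_bh, rep(1, 4))

  expect_error(correctDiagonal(data.frame(p = 0.1, diagonal = FALSE)),
               "diagonal")

  # properties on random p vectors
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    cc <- correctDiagonal(data.frame(p = p, diagonal = TRUE))
    expect_true(all(cc$p_bonferroni >= p - 1e-15))
    expect_true(all(cc$p_bonferroni <= 1))
    expect_true(all(cc$q_bh <= 1 + 1e-15))
    o <- order(p)
    expect_true(all(diff(cc$q_bh[o]) >= -1e-15))  # monotone in rank
  }
})
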