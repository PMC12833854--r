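test_that("baseline CV uses first recorded measurements with exclusions", {
  ts <- makeStudy(A = c(100, 150), B = c(100, 140), C = c(100, 200),
                  days = c(0, 3), groups = rep("G", 3))
  expect_equal(baselineCV(ts)$cv, 0)

  ts2 <- makeStudy(A = c(100, 150), B = c(200, 300), days = c(0, 3),
                   groups = c("G", "G"))
  bc <- baselineCV(ts2)
  expect_equal(bc$cv, 100 * sd(c(100, 200)) / 150, tolerance = 1e-12)
  expect_equal(round(bc$cv, 2), 47.14)

  # nonpositive first measurement excludes the animal
  ts3 <- makeStudy(A = c(-1, 150), B = c(100, 140), C = c(100, 200),
                   days = c(0, 3), groups = rep("G", 3))
  bc3 <- baselineCV(ts3)
  expect_equal(bc3$n, 2)
  expect_equal(bc3$cv, 0)
})

test_that("base score follows the piecewise CV penalty verbatim", {
  expect_equal(homogeneityBaseScore(10), 100)
  expect_equal(homogeneityBaseScore(15), 100)
  expect_equal(homogeneityBaseScore(20), 90)
  expect_equal(homogeneityBaseScore(30), 80)
  expect_equal(homogeneityBaseScore(80), 0)
  # the published piecewise form is discontinuous at pi: applied as defined
  expect_equal(homogeneityBaseScore(30 + 1e-9), 100, tolerance = 1e-6)
  # non-increasing on each branch
  cv1 <- seq(0, 30, by = 0.5); cv2 <- seq(30.1, 120, by = 0.5)
  expect_true(all(diff(homogeneityBaseScore(cv1)) <= 0))
  expect_true(all(diff(homogeneityBaseScore(cv2)) <= 0))
  s <- homogeneityBaseScore(seq(0, 200, by = 1))
  expect_true(all(s >= 0 & s <= 100))
})

test_that("small-sample factor multiplies the two conditional penalties", {
  expect_equal(sampleSizeFactor(10), 1)
  expect_equal(sampleSizeFactor(5), 1)
  expect_equal(sampleSizeFactor(4), 0.9)
  expect_equal(sampleSizeFactor(2), 0.72)
})

test_that("homogeneity assessment composes score, factor and stage", {
  ts <- makeStudy(A = c(100, 150), B = c(200, 300), C = c(120, 160),
                  D = c(140, 170),
                  days = c(0, 3), groups = rep("G", 4))
  h <- as.data.frame(assessHomogeneity(ts))
  expect_equal(h$score, h$base_score * h$factor)
  expect_equal(h$stage, "pre_filter")
  expect_equal(h$factor, 0.9)  # n = 4

  cfg <- homogeneityConfig()
  expect_equal(homogeneityBaseScore(20, cfg) * sampleSizeFactor(4, cfg), 81)
  expect_error(baselineCV(makeStudy(A = c(-1, 2), days = c(0, 3),
                                    groups = "G")), "not computable")
})

test_that("sensitivity tiers map group size to fence parameters", {
  p <- selectSensitivity(4)
  expect_equal(p$level, "ultra_conservative")
  expect_equal(p$iqr_multiplier, 4.0)
  expect_equal(p$growth_limit_pct_per_day, 5000)
  expect_equal(p$decline_limit_pct_per_day, 90)
  expect_true(p$require_multiple_indicators)

  p <- selectSensitivity(8)
  expect_equal(p$level, "conservative")
  expect_equal(p$iqr_multiplier, 3.0)
  p <- selectSensitivity(10)
  expect_equal(p$level, "conservative")
  p <- selectSensitivity(12)
  expect_equal(p$level, "moderate")
  expect_equal(p$iqr_multiplier, 2.0)
  expect_equal(p$growth_limit_pct_per_day, 1000)

  # alternative preset boundaries and manual override
  expect_equal(selectSensitivity(7, preset = "qc")$level,
               "ultra_conservative")
  expect_equal(selectSensitivity(12, preset = "qc")$level, "conservative")
  expect_equal(selectSensitivity(13, preset = "qc")$level, "moderate")
  expect_equal(selectSensitivity(100, level = "ultra_conservative")$level,
               "ultra_conservative")
})

test_that("the six criteria flag what they should and nothing else", {
  # clean monotone exponential cohort: zero flags
  clean <- makeCleanCohort(rep(c(0.18, 0.2, 0.22), 4), rep("G", 12))
  expect_equal(nrow(detectOutliers(clean)), 0)

  # impossible value, critical
  ts <- makeStudy(A = c(100, -1, 400), B = c(100, 210, 400),
                  C = c(95, 200, 410), D = c(105, 190, 400),
                  days = c(0, 3, 7), groups = rep("G", 4))
  f <- as.data.frame(detectOutliers(ts))
  iv <- f[f$criterion == "IMPOSSIBLE_VALUE", ]
  expect_equal(iv$animal_id, "A")
  expect_equal(iv$severity, "critical")
  expect_equal(iv$day, 3)

  # 100 -> 2200 in one day is 2100 %/day: extreme under the moderate tier
  prof <- list(G = selectSensitivity(12))
  ts2 <- makeStudy(A = c(100, 2200, 4000), days = c(0, 1, 2), groups = "G")
  f2 <- as.data.frame(detectOutliers(ts2, prof))
  expect_true("EXTREME_GROWTH" %in% f2$criterion)
  # but tolerated under the ultra-conservative tier (limit 5000 %/day)
  f2u <- as.data.frame(detectOutliers(
    ts2, list(G = selectSensitivity(4))))
  expect_false("EXTREME_GROWTH" %in% f2u$criterion)

  # extreme decline: 90% drop in one day = 90 %/day > 67
  ts3 <- makeStudy(A = c(1000, 100, 120), days = c(0, 1, 2), groups = "G")
  f3 <- as.data.frame(detectOutliers(ts3, prof))
  expect_true("EXTREME_DECLINE" %in% f3$criterion)

  # abrupt final-day drop with no earlier decline, medium severity
  ts4 <- makeStudy(A = c(100, 150, 220, 80), days = c(0, 2, 4, 5),
                   groups = "G")
  f4 <- as.data.frame(detectOutliers(ts4, list(G = selectSensitivity(4))))
  ld <- f4[f4$criterion == "LAST_DAY_DROP", ]
  expect_equal(nrow(ld), 1)
  expect_equal(ld$severity, "medium")
  expect_equal(ld$day, 5)
})

test_that("IQR criteria catch planted spikes within and across animals", {
  set.seed(21)
  sim <- simulateCohort(syntheticSpec(
    group_specs = list(list(label = "G", n_animals = 12, r_mean = 0.2,
                            r_sd = 0.01, N0_gmean = 100, N0_gcv = 10)),
    schedule = c(0, 2, 4, 6, 8, 10, 12), noise_cv = 5, seed = 77))
  study <- sim$study
  b <- burdenMatrix(study)
  b[4, "G_03"] <- b[4, "G_03"] * 10   # single-point 10x spike
  spiked <- TumorStudy(b, days = studyDays(study),
                       groups = unname(groupLabels(study)),
                       unit = "volume_mm3", animalIds = animalIds(study))
  f <- as.data.frame(detectOutliers(spiked))
  hit <- f[f$animal_id == "G_03", ]
  expect_true(any(hit$criterion %in% c("INTRA_OUTLIER", "GROUP_OUTLIER")))
  expect_true(all(f$severity[f$criterion == "INTRA_OUTLIER"] == "high"))
  expect_true(all(f$severity[f$criterion == "GROUP_OUTLIER"] == "medium"))

  # all flags are scale-invariant (log/ratio criteria)
  scaled <- TumorStudy(b * 1e4, days = studyDays(study),
                       groups = unname(groupLabels(study)),
                       unit = "bli_photons_per_s",
                       animalIds = animalIds(study))
  fs <- as.data.frame(detectOutliers(scaled))
  expect_equal(fs[c("animal_id", "day", "criterion")],
               f[c("animal_id", "day", "criterion")])
})

test_that("exclusion recommendations honor the multiple-indicator rule", {
  flags <- S4Vectors::DataFrame(
    animal_id = c("A", "A", "B"), day = c(3, 5, 3),
    criterion = c("INTRA_OUTLIER", "GROUP_OUTLIER", "GROUP_OUTLIER"),
    severity = c("high", "medium", "medium"),
    detail = "")
  groups <- c(A = "G", B = "G")
  profUltra <- list(G = selectSensitivity(4))
  # A has two distinct criteria; B has a single medium flag
  expect_equal(recommendExclusions(flags, profUltra, groups), "A")
  # a single critical flag suffices even under require-multiple
  flags2 <- S4Vectors::DataFrame(animal_id = "B", day = 0,
                                 criterion = "IMPOSSIBLE_VALUE",
                                 severity = "critical", detail = "")
  expect_equal(recommendExclusions(flags2, profUltra, groups), "B")
  # without the rule any flagged animal is recommended
  profMod <- list(G = selectSensitivity(12))
  expect_setequal(recommendExclusions(flags, profMod, groups),
                  c("A", "B"))
})

test_that("filter modes implement complete / animal / point semantics", {
  days <- c(0, 2, 4, 6, 8)
  ts <- makeStudy(A = 100 * exp(0.2 * days), B = 100 * exp(0.21 * days),
                  days = days, groups = c("G", "G"))
  oneFlag <- S4Vectors::DataFrame(animal_id = "A", day = 4,
                                  criterion = "INTRA_OUTLIER",
                                  severity = "high", detail = "")
  expect_identical(applyFilter(ts, oneFlag, "complete"), ts)

  al <- applyFilter(ts, oneFlag, "animal_level")
  expect_equal(animalIds(al), "B")

  # 1 of 5 points flagged: animal kept with 4 valid points
  pl <- applyFilter(ts, oneFlag, "point_level")
  expect_equal(animalIds(pl), c("A", "B"))
  expect_equal(sum(!animalSeries(pl, "A")$excluded), 4)
  # loaded values preserved (non-destructive)
  expect_equal(animalSeries(pl, "A")$value, animalSeries(ts, "A")$value)

  # 3 of 5 points flagged: 2 remain < 3, animal dropped
  threeFlags <- S4Vectors::DataFrame(animal_id = "A", day = c(2, 4, 6),
                                     criterion = "INTRA_OUTLIER",
                                     severity = "high", detail = "")
  pl3 <- applyFilter(ts, threeFlags, "point_level")
  expect_equal(animalIds(pl3), "B")

  # severity selection: medium flags ignored when only critical selected
  medFlag <- S4Vectors::DataFrame(animal_id = "A", day = 4,
                                  criterion = "GROUP_OUTLIER",
                                  severity = "medium", detail = "")
  expect_equal(animalIds(applyFilter(ts, medFlag, "animal_level",
                                     severities = "critical")),
               c("A", "B"))
  # emptying a group warns
  gflag <- S4Vectors::DataFrame(animal_id = c("A", "B"), day = 0,
                                criterion = "IMPOSSIBLE_VALUE",
                                severity = "critical", detail = "")
  ts2 <- makeStudy(A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 2, 3),
                   days = c(0, 1, 2), groups = c("G1", "G1", "G2"))
  expect_warning(applyFilter(ts2, gflag, "animal_level"), "emptied")
})

test_that("point filtering removes flagged measurements for good", {
  set.seed(31)
  sim <- simulateCohort(syntheticSpec(
    group_specs = list(list(label = "G", n_animals = 10, r_mean = 0.2,
                            r_sd = 0.01, N0_gmean = 100, N0_gcv = 10)),
    schedule = c(0, 2, 4, 6, 8, 10), noise_cv = 5, seed = 9,
    outlier_plan = list(list(kind = "spike", count = 1))))
  f1 <- detectOutliers(sim$study)
  expect_gt(nrow(f1), 0)
  filtered <- applyFilter(sim$study, f1, "point_level")
  # every flagged point is excluded in the filtered study ...
  e <- excludedMatrix(filtered)
  days <- studyDays(filtered)
  f1d <- as.data.frame(f1)
  for (k in seq_len(nrow(f1d)))
    expect_true(e[match(f1d$day[k], days), f1d$animal_id[k]])
  # ... and a rerun never resurrects an excluded point
  f2 <- as.data.frame(detectOutliers(filtered))
  if (nrow(f2))
    for (k in seq_len(nrow(f2)))
      expect_false(e[match(f2$day[k], days), f2$animal_id[k]])
})
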