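test_that("count curves align t = 0 to the first persistent 1-to-2 transition", {
  cc <- countCurve(obsFromCounts(c(1, 1, 2, 2, 4)))
  expect_equal(curveTimes(cc)[3], 0)
  expect_equal(rawCounts(cc), c(1, 1, 2, 2, 4))
  expect_error(countCurve(obsFromCounts(c(4, 4, 4))), "first mitosis")
})

test_that("count cleaning removes transient dips and stays monotone", {
  # the curve enters at 2 so alignment needs a leading singleton
  cc <- countCurve(obsFromCounts(c(1, 2, 3, 2, 4)))
  expect_equal(cleanedCounts(cc)[2:5], c(2, 3, 3, 4))
  expect_true(all(diff(cleanedCounts(cc)) >= 0))
})

test_that("stage durations follow the intra/inter definitions exactly", {
  # 2 cells on [0,10), 3 on [10,12), 4 on [12,20), 5-7 on [20,23), 8 on
  # [23,33), then straight to 32 to complete every earlier stage
  counts <- c(rep(2, 10), rep(3, 2), rep(4, 8), rep(6, 3), rep(8, 10), rep(32, 2))
  sd_ <- stageDurations(countCurve(obsFromCounts(c(1, counts))))
  expect_equal(unname(intraDurations(sd_)[c("2", "4", "8")]), c(10, 8, 10))
  expect_equal(unname(interDurations(sd_)[c("3", "5-7")]), c(2, 3))
  # stages the curve never passed are flagged incomplete
  expect_true("32" %in% sd_@incomplete)
  # instantaneous 4 -> 8 jump: zero inter(5-7)
  j <- stageDurations(countCurve(obsFromCounts(c(1, 2, 2, 4, 8, 8, 33))))
  expect_equal(unname(interDurations(j)["5-7"]), 0)
})

test_that("stage durations are invariant to shifting all times", {
  counts <- c(1, rep(2, 5), rep(4, 4), rep(8, 3), rep(16, 4), rep(32, 2), 33)
  obs <- obsFromCounts(counts)
  obs2 <- obs; obs2$time_h <- obs2$time_h + 57.3
  a <- stageDurations(countCurve(obs))
  b <- stageDurations(countCurve(obs2))
  expect_equal(intraDurations(a), intraDurations(b))
  expect_equal(interDurations(a), interDurations(b))
})

test_that("intra plus inter durations conserve the time from t0 to 32 cells", {
  for (s in c(31, 32)) {
    cfg <- simulationConfig(seed = s, roundCV = 0.12)
    cc <- countCurve(simulateLineage(cfg, 1))
    sd_ <- stageDurations(cc)
    tot <- sum(intraDurations(sd_)[c("2", "4", "8", "16")]) +
      sum(interDurations(sd_))
    t32 <- min(curveTimes(cc)[cleanedCounts(cc) >= 32])
    expect_equal(tot, t32, tolerance = 1e-9)
  }
})

test_that("division durations list every blastomere of the round", {
  tr <- handTree(divTimes2 = c(10, 11))
  expect_equal(sort(divisionDurations(tr, 2)), c(10, 11))
  expect_error(divisionDurations(tr, 3), "undivided")
  cfg <- simulationConfig(seed = 14)
  sim <- simulateLineage(cfg, 1)
  expect_length(divisionDurations(sim, 2), 2L)
  expect_length(divisionDurations(sim, 3), 4L)
  expect_length(divisionDurations(sim, 4), 8L)
  # third-round blastomeres all born at 12 h, dividing at 22, 23, 24, 31 h
  nd <- data.frame(
    node_id = 1:15,
    parent_id = c(NA, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 7L, 7L),
    round_index = c(1L, 2L, 2L, rep(3L, 4L), rep(4L, 8L)),
    birth_time = c(0, 5, 5, 12, 12, 12, 12, 22, 22, 23, 23, 24, 24, 31, 31),
    division_time = c(5, 12, 12, 22, 23, 24, 31, rep(NA_real_, 8L)))
  tr3 <- lineageTree("h2", nd)
  expect_equal(sort(divisionDurations(tr3, 3)), c(10, 11, 12, 19))
  expect_equal(durationCV(divisionDurations(tr3, 3)), sqrt(50 / 3) / 13)
})

test_that("the normalized second difference behaves as |d1-d2|/mean", {
  expect_equal(secondDiffNorm(c(10, 10)), 0)
  expect_equal(secondDiffNorm(c(10, 12)), 2 / 11)
  expect_equal(secondDiffNorm(7 * c(10, 12)), secondDiffNorm(c(10, 12)))
  expect_error(secondDiffNorm(c(10, -1)), "positive")
  expect_error(secondDiffNorm(c(1, 2, 3)), "exactly 2")
})

test_that("duration CV is the sample CV and is scale/permutation invariant", {
  d <- c(10, 11, 12, 19)
  expect_equal(durationCV(d), sqrt(50 / 3) / 13)
  expect_equal(durationCV(d), durationCV(rev(d)))
  expect_equal(durationCV(d * 3.7), durationCV(d))
  expect_equal(durationCV(c(5, 5, 5)), 0)
  expect_error(durationCV(9), "at least 2")
})

test_that("synchrony classification is inclusive at the cutoff", {
  expect_equal(classifySynchrony(0.15), "high")
  expect_equal(classifySynchrony(0.149), "low")
  expect_equal(classifySynchrony(0), "low")
  expect_error(classifySynchrony(-0.01), "non-negative")
})

test_that("synchrony profiles summarize a lineage end to end", {
  cfg <- simulationConfig(seed = 18, roundCV = c(0, 0, 0, 0, 0))
  pr <- synchronyProfile(simulateLineage(cfg, 1))
  expect_equal(thirdCV(pr), 0)
  expect_equal(fourthCV(pr), 0)
  expect_equal(synchronyClass(pr), "low")
})
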