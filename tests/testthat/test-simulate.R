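test_that("lineage trees are binary, time-consistent and reach 32 cells", {
  cfg <- simulationConfig(seed = 10)
  tr <- simulateLineage(cfg, 1)
  nd <- nodes(tr)
  expect_equal(sum(nd$round_index == 6L), 32L)
  div <- nd[!is.na(nd$division_time), ]
  kids <- table(nd$parent_id[!is.na(nd$parent_id)])
  expect_true(all(kids == 2L))
  idx <- match(nd$parent_id, nd$node_id)
  expect_equal(nd$birth_time[!is.na(idx)], nd$division_time[idx][!is.na(idx)])
  expect_true(all(div$division_time > div$birth_time))
})

test_that("zero round CV gives identical durations and zero third CV", {
  cfg <- simulationConfig(roundCV = c(0, 0, 0, 0, 0), seed = 3)
  tr <- simulateLineage(cfg, 1)
  d3 <- divisionDurations(tr, 3)
  expect_equal(length(unique(round(d3, 12))), 1L)
  expect_equal(durationCV(d3), 0)
  expect_equal(trueRoundCV(tr, 4), 0)
})

test_that("sample third CV converges to the configured round CV", {
  # Monte-Carlo against the log-normal generator: the sample CV of the
  # pooled third-round durations of 200 embryos (800 draws) approaches the
  # configured 0.2 within 10%. (The mean of per-embryo n = 4 sample CVs is
  # a different, downward-biased quantity, E[s]/sigma ~ 0.92 at n = 4.)
  cfg <- simulationConfig(roundCV = c(0.02, 0.05, 0.2, 0.05, 0.05), seed = 77)
  durs <- unlist(lapply(1:200, function(i)
    divisionDurations(simulateLineage(cfg, i), 3)))
  pooled <- sd(durs) / mean(durs)
  expect_gt(pooled, 0.18)
  expect_lt(pooled, 0.22)
})

test_that("living-cell count from the lineage is monotone non-decreasing", {
  cfg <- simulationConfig(seed = 21)
  tr <- simulateLineage(cfg, 2)
  cc <- countCurve(tr)
  expect_true(all(diff(cleanedCounts(cc)) >= 0))
})

test_that("trajectories stay inside the embryo and respect zero motion", {
  cfg <- simulationConfig(seed = 5, motionStepSD = 0)
  tr <- simulateLineage(cfg, 1)
  obs <- simulateTrajectories(tr, cfg)
  ctr <- cfg@volumeDim * cfg@voxelSpacing / 2
  dx <- cfg@voxelSpacing[1]
  r <- sqrt((obs$x * dx - ctr[1])^2 + (obs$y * dx - ctr[2])^2 +
              (obs$z * dx - ctr[3])^2)
  expect_true(all(r <= cfg@embryoRadius + 1e-9))
  # zero step SD: a cell never moves except by excluded-volume contacts,
  # which cannot occur before any neighbour exists
  one <- obs[obs$node_id == 1, ]
  expect_true(all(abs(diff(one$x)) < 1e-12))
  expect_true(all(abs(diff(one$y)) < 1e-12))
})

test_that("trajectory generation is bit-identical under a fixed seed", {
  cfg <- simulationConfig(seed = 8)
  tr <- simulateLineage(cfg, 1)
  a <- simulateTrajectories(tr, cfg)
  b <- simulateTrajectories(tr, cfg)
  expect_identical(a, b)
})

test_that("rendering reproduces geometry: empty, symmetric and peaked", {
  cfg <- simulationConfig(seed = 1, noiseSD = 0, zAttenuation = 0,
                          volumeDim = c(64L, 64L, 32L))
  empty <- renderFrame(data.frame(x = numeric(), y = numeric(), z = numeric()), cfg)
  expect_equal(max(intensities(empty)), 0)
  # one nucleus centered on slice 16 (0-based 15): z symmetric about it
  obs <- data.frame(x = 32, y = 32, z = 15 * 2.5)
  v <- intensities(renderFrame(obs, cfg))
  prof <- apply(v, 3, max)
  expect_equal(prof[16 - (1:3)], prof[16 + (1:3)], tolerance = 1e-12)
  # argmax voxel equals the nucleus voxel
  w <- which(v == max(v), arr.ind = TRUE)[1, ]
  expect_equal(unname(w), c(33, 33, 16))
})

test_that("cohort truth CVs equal sample CVs recomputed from the lineages", {
  cfg <- simulationConfig(nEmbryos = 3, seed = 12)
  coh <- simulateCohort(cfg)
  for (i in 1:3)
    expect_equal(coh$truth$true_third_cv[i], trueRoundCV(coh$lineages[[i]], 3))
  expect_true(all(coh$truth$outcome %in% c("born", "abort")))
})
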