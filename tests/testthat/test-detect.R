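cfgSmall <- simulationConfig(seed = 2, volumeDim = c(64L, 64L, 32L))

test_that("preprocess removes flat background and isolated impulses", {
  d <- c(32L, 32L, 16L)
  const <- voxelGrid(array(0.7, d), spacing = c(0.8, 0.8, 2))
  out <- preprocessFrame(const, detectionParams())
  expect_equal(max(intensities(out)), 0)
  imp <- array(0, d); imp[16, 16, 8] <- 1
  out2 <- preprocessFrame(voxelGrid(imp, spacing = c(0.8, 0.8, 2)),
                          detectionParams(denoiseRadius = 1L))
  expect_equal(max(intensities(out2)), 0)
  zero <- voxelGrid(array(0, d), spacing = c(0.8, 0.8, 2))
  expect_identical(intensities(preprocessFrame(zero)), intensities(zero))
})

test_that("preprocessed two-nucleus fixture peaks inside a true nucleus", {
  set.seed(41)
  obs <- data.frame(x = c(20, 44), y = c(20, 44), z = c(20, 60))
  vg <- renderFrame(obs, cfgSmall)
  v <- intensities(preprocessFrame(vg))
  w <- which(v == max(v), arr.ind = TRUE)[1, ] - 1  # 0-based
  dz <- 2.5
  dists <- sqrt((obs$x - w[1])^2 + (obs$y - w[2])^2 + (obs$z - w[3] * dz)^2)
  expect_lt(min(dists), cfgSmall@nucleusRadius / 0.8)
})

test_that("z-bias correction flattens depth attenuation and respects no-ops", {
  cfg <- simulationConfig(seed = 1, zAttenuation = 0.012, noiseSD = 0.02)
  set.seed(7)
  obs <- data.frame(x = c(40, 64, 88), y = c(40, 64, 88), z = c(25, 75, 130))
  pre <- preprocessFrame(renderFrame(obs, cfg))
  zc <- correctZBias(pre)
  peakNear <- function(v, zIso) {
    iz <- round(zIso / 2.5) + 1
    max(v[, , max(1, iz - 1):min(dim(v)[3], iz + 1)])
  }
  pk <- vapply(obs$z, function(z) peakNear(intensities(zc), z), numeric(1))
  expect_lt((max(pk) - min(pk)) / mean(pk), 0.1)
  # z-uniform volume: unchanged up to a global factor
  u <- voxelGrid(array(rep(0.4, 32 * 32 * 16), c(32, 32, 16)),
                 spacing = c(0.8, 0.8, 2))
  ratio <- intensities(correctZBias(u)) / intensities(u)
  expect_equal(max(ratio) - min(ratio), 0)
  # empty volume unchanged
  e <- voxelGrid(array(0, c(16, 16, 8)), spacing = c(0.8, 0.8, 2))
  expect_identical(intensities(correctZBias(e)), intensities(e))
})

test_that("binarize finds single components, drops speckle, and is idempotent", {
  d <- c(48L, 48L, 24L)
  expect_false(any(binarizeFrame(voxelGrid(array(0, d), spacing = c(0.8, 0.8, 2)))))
  set.seed(31)
  one <- renderFrame(data.frame(x = 24, y = 24, z = 30),
                     simulationConfig(seed = 3, volumeDim = d))
  mask <- binarizeFrame(correctZBias(preprocessFrame(one)))
  lab <- EmbryoSynchrony:::cpp_label3d(mask, dim(mask))
  expect_equal(max(lab), 1L)
  # sphere plus a 3-voxel speckle with min_component_size = 10 -> 1 component
  m <- array(FALSE, d)
  m <- addBall(m, c(24, 24, 12), 5)
  m[40, 40, 20] <- m[41, 40, 20] <- m[42, 40, 20] <- TRUE
  vgm <- voxelGrid(m + 0, spacing = c(1, 1, 1))
  keep <- binarizeFrame(vgm, detectionParams(minComponentSize = 10L))
  expect_equal(max(EmbryoSynchrony:::cpp_label3d(keep, d)), 1L)
  # idempotence: binarizing a mask returns the mask
  again <- binarizeFrame(voxelGrid(keep + 0, spacing = c(1, 1, 1)),
                         detectionParams(minComponentSize = 10L))
  expect_identical(again, keep)
})

test_that("oversize submasks are split by watershed, others left alone", {
  m <- array(FALSE, c(96L, 96L, 48L))
  r <- 5
  centers <- rbind(c(15, 15, 10), c(45, 15, 10), c(75, 15, 10), c(15, 45, 10),
                   c(75, 45, 10), c(15, 75, 10), c(45, 75, 10), c(75, 75, 10))
  for (i in 1:8) m <- addBall(m, centers[i, ], r)
  m <- addBall(m, c(40, 45, 35), r)
  m <- addBall(m, c(40 + 1.5 * r, 45, 35), r)   # touching pair
  lab <- subdivideMask(m, detectionParams(), spacing = c(1, 1, 1))
  expect_equal(max(lab), 10L)
  # all labels same size: no subdivision at all
  m2 <- array(FALSE, c(64L, 64L, 32L))
  for (cx in c(16, 48)) for (cy in c(16, 48)) m2 <- addBall(m2, c(cx, cy, 16), r)
  lab2 <- subdivideMask(m2, detectionParams(), spacing = c(1, 1, 1))
  expect_equal(max(lab2), 4L)
  expect_equal(sum(lab2 > 0), sum(m2))
})

test_that("the subdivision iteration cap limits the number of split rounds", {
  m <- array(FALSE, c(96L, 64L, 32L))
  r <- 5
  # three chained balls plus five well-separated singles
  m <- addBall(m, c(20, 32, 16), r)
  m <- addBall(m, c(20 + 1.5 * r, 32, 16), r)
  m <- addBall(m, c(20 + 3 * r, 32, 16), r)
  singles <- rbind(c(60, 12, 16), c(60, 28, 16), c(60, 44, 16),
                   c(80, 12, 16), c(80, 28, 16))
  for (i in 1:5) m <- addBall(m, singles[i, ], r)
  capped <- subdivideMask(m, detectionParams(maxSubdivisionIters = 1L),
                          spacing = c(1, 1, 1))
  full <- subdivideMask(m, detectionParams(), spacing = c(1, 1, 1))
  expect_lte(max(capped), max(full))
  expect_equal(max(full), 8L)
})

test_that("centroids follow the z-division convention and match ground truth", {
  cfg <- cfgSmall
  # nucleus centered on slice index 10 -> isotropic z = 25
  obs <- data.frame(x = 32, y = 32, z = 10 * 2.5)
  set.seed(11)
  vg <- renderFrame(obs, cfg)
  det <- detectFrame(vg, embryoId = "z10")
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$z - 25), 1.25)
  expect_equal(sliceIndex(25, 2.5), 10)
  # empty label image -> empty observation list
  lab0 <- array(0L, c(16L, 16L, 8L))
  e <- measureCentroids(lab0, voxelGrid(array(0, c(16, 16, 8)),
                                        spacing = c(0.8, 0.8, 2)))
  expect_equal(nrow(e), 0L)
})

test_that("detectFrame recovers counts and centroids on a rendered frame", {
  cfg <- simulationConfig(seed = 6)
  set.seed(61)
  truth <- placeSeparated(8, cfg)
  vg <- renderFrame(truth, cfg)
  det <- detectFrame(vg, embryoId = "fx8")
  expect_equal(nrow(det), 8L)
  pr <- EmbryoSynchrony:::matchPoints(as.matrix(truth),
                                      as.matrix(det[, c("x", "y", "z")]))
  err <- sqrt(rowSums((as.matrix(truth)[pr[, 1], ] -
                         as.matrix(det[pr[, 2], c("x", "y", "z")]))^2))
  expect_lt(mean(err), cfg@nucleusRadius / cfg@voxelSpacing[1])
  # determinism: identical output for the same frame
  expect_identical(det, detectFrame(vg, embryoId = "fx8"))
  # empty volume -> empty list
  e <- detectFrame(voxelGrid(array(0, c(32, 32, 16)), spacing = c(0.8, 0.8, 2)))
  expect_equal(nrow(e), 0L)
})

test_that("manual corrections add, move, remove and keep an audit trail", {
  obs <- data.frame(embryo_id = "e1", frame = c(1L, 1L, 2L),
                    time_h = c(0, 0, 1), x = c(1, 2, 1), y = 0, z = 0,
                    volume = NA_real_)
  expect_equal(nrow(applyManualCorrections(obs, obs[0, ])), 3L)
  add <- data.frame(action = "add", obs_id = NA, embryo_id = "e1", frame = 2L,
                    time_h = 1, x = 5, y = 5, z = 5)
  out <- applyManualCorrections(obs, add)
  expect_equal(nrow(out), 4L)
  expect_length(attr(out, "audit"), 1L)
  # remove then add on the same frame: net count unchanged
  edits <- rbind(data.frame(action = "remove", obs_id = 1, embryo_id = "e1",
                            frame = 1L, time_h = 0, x = NA, y = NA, z = NA),
                 add)
  out2 <- applyManualCorrections(obs, edits)
  expect_equal(nrow(out2), nrow(obs))
  expect_error(applyManualCorrections(obs, data.frame(
    action = "remove", obs_id = 99, embryo_id = "e1", frame = 1L,
    time_h = 0, x = NA, y = NA, z = NA)), "not found")
})
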