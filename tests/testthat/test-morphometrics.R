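test_that("distance CV matches a brute-force oracle and its symmetries", {
  # square vertices: all distances to the barycenter equal
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(distanceCV(sq), 0)
  # brute-force arithmetic oracle for a collinear triple
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  expect_equal(distanceCV(pts), sd(d) / mean(d))
  # scale invariance
  expect_equal(distanceCV(pts * 11.3), distanceCV(pts))
  # rigid-motion invariance
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(distanceCV(pts %*% R + 5), distanceCV(pts))
  # coincident points are defined as zero
  expect_equal(distanceCV(rbind(c(1, 1, 1), c(1, 1, 1))), 0)
})

test_that("motility sums matched displacements per unit time", {
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(motility(a, a, 1), 0)
  b <- a; b[, 2] <- b[, 2] + 1          # both nuclei displaced 1 unit
  expect_equal(motility(a, b, 0.5), 4)  # 2 units over half an hour
  expect_equal(motility(a, b, 0.5), motility(b, a, 0.5))
  # division: the extra point is excluded from the default sum
  b2 <- rbind(b, c(10, 3, 0))
  expect_equal(motility(a, b2, 0.5), 4)
  expect_gt(motility(a, b2, 0.5, splitUnmatched = TRUE), 4)
  expect_error(motility(a[0, , drop = FALSE], b, 1), "at least one point")
})

test_that("Procrustes distance vanishes exactly on similarity transforms", {
  set.seed(20)
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(procrustesDistance(x, x, corresponded = TRUE), 0)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  y <- 2.7 * x %*% R
  y <- sweep(y, 2, c(3, -1, 8), `+`)
  expect_lt(procrustesDistance(x, y, corresponded = TRUE), 1e-9)
  # symmetry and non-negativity
  set.seed(21)
  z <- matrix(rnorm(15), 5, 3)
  expect_equal(procrustesDistance(x, z, corresponded = TRUE),
               procrustesDistance(z, x, corresponded = TRUE), tolerance = 1e-9)
  expect_gt(procrustesDistance(x, z, corresponded = TRUE), 0)
  expect_error(procrustesDistance(matrix(1, 5, 3), x), "degenerate")
})

test_that("Procrustes agrees with a numeric rotation-search oracle", {
  # oracle: optimal proper rotation found by direct minimization over Euler
  # angles of the residual between unit-size centered shapes
  oracle <- function(a, b) {
    pre <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
    a <- pre(a); b <- pre(b)
    rotmat <- function(p) {
      cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
      cz <- cos(p[3]); sz <- sin(p[3])
      rbind(c(cy * cz, -cy * sz, sy),
            c(sx * sy * cz + cx * sz, -sx * sy * sz + cx * cz, -sx * cy),
            c(-cx * sy * cz + sx * sz, cx * sy * sz + sx * cz, cx * cy))
    }
    f <- function(p) {
      br <- b %*% rotmat(p[1:3])
      # optimal scale for unit shapes; scale must be positive, otherwise a
      # negative scale smuggles a reflection past the rotation constraint
      beta <- max(0, sum(a * br))
      sum((a - beta * br)^2)
    }
    best <- Inf
    for (st in list(c(0, 0, 0), c(1, 1, 1), c(2, -1, 0.5), c(-2, 0.3, 2)))
      best <- min(best, optim(st, f, method = "Nelder-Mead",
                              control = list(maxit = 2000, reltol = 1e-14))$value)
    sqrt(max(0, best))
  }
  set.seed(33)
  for (i in 1:3) {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    expect_equal(procrustesDistance(a, b, corresponded = TRUE), oracle(a, b),
                 tolerance = 1e-5)
  }
})

test_that("Procrustes squared distance matches vegan on reflection-free pairs", {
  set.seed(44)
  a <- matrix(rnorm(18), 6, 3)
  # rotate + perturb slightly so the optimal map is a proper rotation
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  b <- a %*% R + matrix(rnorm(18, 0, 0.05), 6, 3)
  d <- procrustesDistance(a, b, corresponded = TRUE)
  ss <- vegan::procrustes(a, b, symmetric = TRUE)$ss
  expect_equal(d^2, ss, tolerance = 1e-6)
})

test_that("unlabeled correspondence search matches the labeled answer", {
  set.seed(55)
  x <- matrix(rnorm(12, sd = 3), 4, 3)
  th <- 1.2
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  y <- (1.5 * x %*% R)[c(3, 1, 4, 2), ]   # permuted similarity copy
  expect_lt(procrustesDistance(x, y), 1e-9)
  # greedy initialization resolves correspondence on well-separated shapes
  # under a modest rotation (its documented operating regime)
  set.seed(56)
  big <- matrix(rnorm(27, sd = 10), 9, 3)       # n = 9 -> greedy path
  ths <- 0.05
  Rs <- rbind(c(cos(ths), 0, sin(ths)), c(0, 1, 0), c(-sin(ths), 0, cos(ths)))
  pb <- big[sample(9), ] %*% Rs
  expect_lt(procrustesDistance(big, pb), 1e-6)
})

test_that("morphometric series reports per-frame descriptors", {
  cfg <- simulationConfig(seed = 23)
  tr <- simulateLineage(cfg, 1)
  obs <- simulateTrajectories(tr, cfg)
  obs <- obs[obs$frame <= 30, ]
  ms <- morphometricSeries(obs)
  expect_equal(nrow(ms), 30L)
  expect_true(all(ms$motility[-1] >= 0, na.rm = TRUE))
  expect_true(all(ms$distance_cv >= 0, na.rm = TRUE))
})
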