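test_that("the test-selection policy picks the tests the data call for", {
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50, 0, 2)       # 4-fold variance ratio
  r <- compareGroups(x, y)
  expect_equal(r$test_name, "welch_t")
  expect_equal(r$p_value, t.test(x, y)$p.value)
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40, 0.5)
  r2 <- compareGroups(a, b)
  expect_equal(r2$test_name, "student_t")
  expect_equal(r2$p_value, t.test(a, b, var.equal = TRUE)$p.value)
  set.seed(3)
  e <- rexp(40); f <- rexp(40, 0.5)          # fails normality -> rank test
  r3 <- compareGroups(e, f)
  expect_equal(r3$test_name, "wilcoxon")
  expect_equal(r3$p_value, wilcox.test(e, f, exact = FALSE)$p.value)
  # identical constant groups are degenerate with p = 1
  r4 <- compareGroups(rep(2, 5), rep(2, 5))
  expect_true(r4$degenerate)
  expect_gte(r4$p_value, 0.99)
  # identical continuous samples: no evidence of difference
  set.seed(4)
  s <- rnorm(30)
  expect_gte(compareGroups(s, s)$p_value, 0.99)
})

test_that("the policy holds its nominal type-I error level", {
  set.seed(1234)
  rej <- 0L
  for (i in 1:2000) {
    x <- rnorm(30); y <- rnorm(30)
    if (compareGroups(x, y)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 2000, 0.035)
  expect_lte(rej / 2000, 0.065)
})

test_that("the two-proportion test matches the corrected chi-square formula", {
  # equal proportions: corrected p exactly 1
  expect_equal(twoProportionTest(5, 10, 5, 10), 1)
  # symmetry in the two groups
  expect_equal(twoProportionTest(4, 34, 19, 40), twoProportionTest(19, 40, 4, 34))
  # direct 2x2 Yates formula oracle on small tables
  yatesP <- function(k1, n1, k2, n2) {
    a <- k1; b <- n1 - k1; c_ <- k2; d <- n2 - k2; n <- n1 + n2
    chi <- n * max(0, abs(a * d - b * c_) - n / 2)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    pchisq(chi, 1, lower.tail = FALSE)
  }
  for (tab in list(c(3, 12, 8, 15), c(1, 9, 6, 11), c(10, 20, 4, 18))) {
    expect_equal(twoProportionTest(tab[1], tab[2], tab[3], tab[4]),
                 yatesP(tab[1], tab[2], tab[3], tab[4]), tolerance = 1e-12)
  }
  expect_error(twoProportionTest(1, 0, 1, 5), "positive")
  expect_error(twoProportionTest(7, 5, 1, 5), "0 <= k <= n")
})

test_that("Spearman correlation uses mid-ranks and two-sided p values", {
  expect_equal(spearmanCorrelation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCorrelation(1:10, -(1:10))$rho, -1)
  set.seed(5)
  x <- rnorm(25); y <- x + rnorm(25)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  got <- spearmanCorrelation(x, y)
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-9)
  expect_equal(got$p_value, ref$p.value)
  # mid-rank oracle for rho
  rhoByHand <- cor(rank(x), rank(y))
  expect_equal(got$rho, rhoByHand, tolerance = 1e-12)
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
})

test_that("count-curve comparison flags only genuinely divergent times", {
  mkCurve <- function(counts) countCurve(obsFromCounts(c(1, counts)))
  base <- c(rep(2, 10), rep(4, 10), rep(8, 20))
  gA <- lapply(1:8, function(i) mkCurve(base))
  res <- compareCountCurves(gA, gA, times = c(5, 15, 25))
  expect_false(any(res$significant))
  # groups diverging only after t = 30 h
  early <- c(rep(2, 15), rep(4, 15), rep(8, 21))
  late <- c(rep(2, 15), rep(4, 15), rep(8, 5), rep(16, 16))
  gB <- lapply(1:8, function(i) mkCurve(early))
  gC <- lapply(1:8, function(i) mkCurve(late))
  res2 <- compareCountCurves(gB, gC, times = c(10, 20, 35, 45))
  expect_true(all(res2$time_h[res2$significant] >= 30))
  # a single requested time equals the generic rank-test path
  va <- vapply(gB, function(cu) cleanedCounts(cu)[findInterval(35, curveTimes(cu))],
               numeric(1))
  vb <- vapply(gC, function(cu) cleanedCounts(cu)[findInterval(35, curveTimes(cu))],
               numeric(1))
  ref <- suppressWarnings(wilcox.test(va, vb, exact = FALSE))$p.value
  expect_equal(compareCountCurves(gB, gC, times = 35)$p_value, ref)
})

test_that("ROC metrics equal brute-force confusion counting at every cutoff", {
  bruteRoc <- function(scores, labels, cutoffs) {
    t(vapply(cutoffs, function(ct) {
      pred <- scores >= ct
      pos <- labels == "abort"
      c(sens = sum(pred & pos) / sum(pos),
        spec = sum(!pred & !pos) / sum(!pos),
        acc = mean(pred == pos))
    }, numeric(3)))
  }
  set.seed(6)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    sc <- round(runif(n), 2)
    lb <- sample(c("born", "abort"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    roc <- rocAnalysis(sc, lb)
    ref <- bruteRoc(sc, lb, roc@cutoffs)
    expect_equal(roc@sensitivity, unname(ref[, "sens"]))
    expect_equal(roc@specificity, unname(ref[, "spec"]))
    expect_equal(roc@accuracy, unname(ref[, "acc"]))
    expect_true(all(diff(roc@sensitivity) <= 1e-12))
    expect_true(all(diff(roc@specificity) >= -1e-12))
  }
})

test_that("ROC selection favors accuracy and separates perfect scores", {
  sc <- c(0.05, 0.06, 0.08, 0.2, 0.25, 0.3)
  lb <- c("born", "born", "born", "abort", "abort", "abort")
  roc <- rocAnalysis(sc, lb)
  expect_equal(max(roc@accuracy), 1)
  expect_equal(unname(rocAt(roc, selectedCutoff(roc))["accuracy"]), 1)
  expect_error(rocAnalysis(sc, rep("born", 6)), "both classes")
})

test_that("ROC of random scores has null area near one half", {
  set.seed(7)
  aucs <- vapply(1:10000, function(i) {
    rocAUC(runif(20), rep(c("born", "abort"), each = 10))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the cohort report tabulates high-CV fractions and born rates", {
  profiles <- data.frame(
    embryo_id = sprintf("m%02d", 1:12),
    third_cv = c(0.2, 0.18, 0.05, 0.06, 0.07, 0.08, 0.04, 0.09, 0.1, 0.11,
                 0.03, 0.02))
  outcomes <- data.frame(embryo_id = profiles$embryo_id,
                         outcome = c("abort", "abort", "abort", "abort",
                                     rep("born", 8)))
  rep_ <- cohortReport(profiles, outcomes)
  expect_equal(rep_$high_fraction_abort_pct, 100 * 2 / 4)
  expect_equal(rep_$high_fraction_all_pct, 100 * 2 / 12)
  expect_equal(rep_$born_rate_high, 0)
  expect_equal(rep_$born_rate_low, 0.8)
  # all-low cohort: proportion test skipped with a warning
  lowProf <- transform(profiles, third_cv = third_cv * 0 + 0.05)
  expect_warning(repLow <- cohortReport(lowProf, outcomes), "skipped")
  expect_equal(repLow$high_fraction_all_pct, 0)
  expect_true(is.na(repLow$prop_test_p))
  # orphan ids are an error
  expect_error(cohortReport(profiles, outcomes[-1, ]), "without a match")
})
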