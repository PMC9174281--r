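## outcome statistics: test-selection policy, proportion test, correlation,
## per-time count comparison, ROC cutoff analysis and the cohort report.

#' Compare two groups with the study's test-selection policy
#'
#' Policy \code{"paper"}: both groups are tested for normality with the
#' estimated-parameter Kolmogorov-Smirnov (Lilliefors) test at alpha = 0.05;
#' if both pass, variances are compared by the F test, and the groups by
#' Student's t test (equal variances) or Welch's t test (unequal);
#' otherwise by the Wilcoxon rank-sum test. All tests two-sided. Groups
#' smaller than 4 (below the Lilliefors minimum) fall through to the rank
#' test. \code{policy = "wilcoxon"} forces the rank test.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param policy "paper" or "wilcoxon".
#' @param alpha significance level of the normality and variance gates.
#' @return a list of class \code{"groupTest"}: test_name, statistic, p_value,
#'   normality_p (per group), variance_ratio_p, n (per group), degenerate.
#' @examples
#' set.seed(1)
#' compareGroups(rnorm(30), rnorm(30, 1))
#' @export
compareGroups <- function(x, y, policy = c("paper", "wilcoxon"), alpha = 0.05) {
  policy <- match.arg(policy)
  if (length(x) < 3L || length(y) < 3L) stop("each group needs n >= 3")
  res <- list(test_name = NA_character_, statistic = NA_real_,
              p_value = NA_real_, normality_p = c(NA_real_, NA_real_),
              variance_ratio_p = NA_real_, n = c(length(x), length(y)),
              degenerate = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    res$test_name <- "degenerate"
    res$p_value <- 1
    res$degenerate <- TRUE
    class(res) <- "groupTest"
    return(res)
  }
  normP <- function(v) {
    if (length(v) < 4L || sd(v) == 0) return(0)  # cannot claim normality
    nortest::lillie.test(v)$p.value
  }
  useRank <- policy == "wilcoxon"
  if (!useRank) {
    res$normality_p <- c(normP(x), normP(y))
    if (all(res$normality_p > alpha)) {
      ft <- stats::var.test(x, y)
      res$variance_ratio_p <- ft$p.value
      tt <- stats::t.test(x, y, var.equal = ft$p.value > alpha)
      res$test_name <- if (ft$p.value > alpha) "student_t" else "welch_t"
      res$statistic <- unname(tt$statistic)
      res$p_value <- tt$p.value
    } else useRank <- TRUE
  }
  if (useRank) {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    res$test_name <- "wilcoxon"
    res$statistic <- unname(wt$statistic)
    res$p_value <- wt$p.value
  }
  class(res) <- "groupTest"
  res
}

#' @export
print.groupTest <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %d/%d)\n", x$test_name,
              x$statistic, x$p_value, x$n[1], x$n[2]))
  invisible(x)
}

#' Two-sided two-proportion test
#'
#' Chi-square two-proportion test with Yates continuity correction (the
#' default of \code{\link[stats]{prop.test}}).
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2.
#' @param correct apply continuity correction.
#' @return two-sided p value.
#' @examples
#' twoProportionTest(4, 34, 19, 40)  # ~0.002
#' @export
twoProportionTest <- function(k1, n1, k2, n2, correct = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("need 0 <= k <= n")
  suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                    correct = correct))$p.value
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties and a two-sided p value.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list(rho, p_value).
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L)
    stop("need equal lengths >= 4")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: ranks undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

# previous-value (step) interpolation of a count curve at time t, NA beyond
# support
countAt <- function(curve, t) {
  times <- curveTimes(curve)
  cc <- cleanedCounts(curve)
  if (t < times[1]) return(NA_real_)
  cc[findInterval(t, times)]
}

#' Compare count curves of two groups at fixed times
#'
#' At each requested time (hours after first mitosis) the per-embryo cleaned
#' counts are read off by previous-value interpolation and the groups
#' compared by the Wilcoxon rank-sum test; times with p below \code{alpha}
#' are flagged. Embryos whose recording does not cover a requested time are
#' excluded from that time with a warning. P values are reported raw by
#' default; \code{adjust} applies \code{\link[stats]{p.adjust}}.
#'
#' @param groupA,groupB lists of \linkS4class{CountCurve}.
#' @param times numeric vector of times, hours.
#' @param alpha flagging level.
#' @param adjust multiple-testing correction method ("none" by default).
#' @return data.frame: time_h, n_a, n_b, statistic, p_value, significant.
#' @export
compareCountCurves <- function(groupA, groupB, times, alpha = 0.05,
                               adjust = "none") {
  rows <- lapply(times, function(t) {
    va <- vapply(groupA, countAt, numeric(1), t = t)
    vb <- vapply(groupB, countAt, numeric(1), t = t)
    if (anyNA(c(va, vb)))
      warning(sum(is.na(c(va, vb))), " embryo(s) excluded at t = ", t,
              " h (beyond curve support)", call. = FALSE)
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE))
    data.frame(time_h = t, n_a = length(va), n_b = length(vb),
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_value[!is.finite(out$p_value)] <- 1   # tied-everywhere groups
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- out$p_value < alpha
  out
}

#' ROC cutoff analysis of a synchrony score
#'
#' Sweeps every unique score and every midpoint between adjacent unique
#' scores as a cutoff; predictions are positive ("abort") when
#' score >= cutoff. Sensitivity is TP/(TP+FN) over aborts, specificity
#' TN/(TN+FP) over borns, accuracy (TP+TN)/n. The selected cutoff maximizes
#' the criterion (accuracy by default, Youden's J optionally), ties broken
#' toward higher specificity and then the lower cutoff.
#'
#' @param scores numeric scores (e.g. third-round duration CVs).
#' @param labels outcome labels, "born" or "abort" (abort = positive class).
#' @param criterion "accuracy" or "youden".
#' @return a \linkS4class{RocSummary}.
#' @examples
#' sc <- c(0.05, 0.08, 0.1, 0.12, 0.18, 0.2, 0.22)
#' lb <- c("born", "born", "born", "abort", "abort", "abort", "abort")
#' rocAnalysis(sc, lb)
#' @export
rocAnalysis <- function(scores, labels, criterion = c("accuracy", "youden")) {
  criterion <- match.arg(criterion)
  labels <- as.character(labels)
  if (!all(labels %in% c("born", "abort")))
    stop("labels must be 'born' or 'abort'")
  pos <- labels == "abort"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  u <- sort(unique(scores))
  cutoffs <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  sens <- spec <- acc <- numeric(length(cutoffs))
  nP <- sum(pos); nN <- sum(!pos)
  for (i in seq_along(cutoffs)) {
    pred <- scores >= cutoffs[i]
    tp <- sum(pred & pos); tn <- sum(!pred & !pos)
    sens[i] <- tp / nP
    spec[i] <- tn / nN
    acc[i] <- (tp + tn) / length(scores)
  }
  crit <- if (criterion == "accuracy") acc else sens + spec - 1
  best <- which(crit == max(crit))
  best <- best[spec[best] == max(spec[best])]
  sel <- cutoffs[best[1]]
  new("RocSummary", cutoffs = cutoffs, sensitivity = sens,
      specificity = spec, accuracy = acc, selectedCutoff = sel,
      selectionCriterion = criterion, nPositive = as.integer(nP),
      nNegative = as.integer(nN))
}

#' Metrics of a RocSummary at a given cutoff
#'
#' @param roc a \linkS4class{RocSummary}.
#' @param cutoff cutoff value (must be one of the swept cutoffs, or metrics
#'   are recomputed are at the nearest swept cutoff below it).
#' @return named numeric: sensitivity, specificity, accuracy.
#' @export
rocAt <- function(roc, cutoff) {
  i <- which(abs(roc@cutoffs - cutoff) < 1e-12)
  if (!length(i)) i <- max(which(roc@cutoffs <= cutoff))
  c(sensitivity = roc@sensitivity[i[1]], specificity = roc@specificity[i[1]],
    accuracy = roc@accuracy[i[1]])
}

#' Area under the ROC curve of a score
#'
#' Rank-based (Mann-Whitney) AUC of scores against born/abort labels, abort
#' positive.
#'
#' @param scores numeric scores.
#' @param labels "born"/"abort" labels.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  pos <- labels == "abort"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Cohort-level synchrony report
#'
#' Cross-tabulates synchrony class against outcome: the high-CV fraction
#' among aborts and among all embryos, the born rate within the high and low
#' classes, and the two-proportion test comparing them.
#'
#' @param profiles list of \linkS4class{SynchronyProfile}, or a data.frame
#'   with columns embryo_id and third_cv.
#' @param outcomes data.frame with columns embryo_id and outcome
#'   ("born"/"abort").
#' @param cutoff high/low cutoff on the third CV.
#' @return a list of class \code{"cohortReport"}: counts, fractions
#'   (percent), born rates and the proportion-test p value.
#' @export
cohortReport <- function(profiles, outcomes, cutoff = 0.15) {
  if (is.data.frame(profiles)) {
    df <- data.frame(embryo_id = profiles$embryo_id,
                     third_cv = profiles$third_cv)
  } else {
    df <- data.frame(
      embryo_id = vapply(profiles, embryoId, character(1)),
      third_cv = vapply(profiles, thirdCV, numeric(1)))
  }
  orphans <- c(setdiff(df$embryo_id, outcomes$embryo_id),
               setdiff(outcomes$embryo_id, df$embryo_id))
  if (length(orphans))
    stop("embryo ids without a match: ", paste(orphans, collapse = ", "))
  df$outcome <- outcomes$outcome[match(df$embryo_id, outcomes$embryo_id)]
  df$class <- classifySynchrony(df$third_cv, cutoff)
  high <- df$class == "high"
  abort <- df$outcome == "abort"
  nHigh <- sum(high); nLow <- sum(!high)
  rep_ <- list(
    cutoff = cutoff,
    n = nrow(df),
    n_abort = sum(abort),
    n_high = nHigh,
    high_fraction_abort_pct = if (sum(abort)) 100 * sum(high & abort) / sum(abort) else NA_real_,
    high_fraction_all_pct = 100 * nHigh / nrow(df),
    born_rate_high = if (nHigh) sum(!abort & high) / nHigh else NA_real_,
    born_rate_low = if (nLow) sum(!abort & !high) / nLow else NA_real_,
    prop_test_p = NA_real_)
  if (nHigh > 0 && nLow > 0) {
    rep_$prop_test_p <- twoProportionTest(sum(!abort & high), nHigh,
                                          sum(!abort & !high), nLow)
  } else {
    warning("one synchrony class is empty; proportion test skipped",
            call. = FALSE)
  }
  class(rep_) <- "cohortReport"
  rep_
}

#' @export
print.cohortReport <- function(x, ...) {
  cat(sprintf("Cohort of %d embryos (cutoff %.2f): %d high-CV, %d abort\n",
              x$n, x$cutoff, x$n_high, x$n_abort))
  cat(sprintf("  high-CV fraction: %.1f%% of aborts, %.1f%% of all\n",
              x$high_fraction_abort_pct, x$high_fraction_all_pct))
  cat(sprintf("  born rate: high %.3f vs low %.3f (prop-test p = %.4g)\n",
              x$born_rate_high, x$born_rate_low, x$prop_test_p))
  invisible(x)
}
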