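## count curves, stage durations and the synchrony statistics.

newCountCurve <- function(embryoId, times, raw, cleaned) {
  new("CountCurve", embryoId = as.character(embryoId), times = times,
      rawCounts = as.numeric(raw), cleanedCounts = as.numeric(cleaned))
}

# first persistent transition from < 2 to >= 2 detected cells
firstMitosisIndex <- function(counts) {
  n <- length(counts)
  for (i in seq_len(n)[-1]) {
    if (counts[i - 1] < 2 && counts[i] >= 2 &&
        (i == n || counts[i + 1] >= 2)) return(i)
  }
  NA_integer_
}

#' @rdname countCurve
setMethod("countCurve", "data.frame", function(x, ...) {
  obs <- asObservations(x)
  ids <- unique(obs$embryo_id)
  if (length(ids) != 1L) stop("countCurve expects a single embryo")
  byFrame <- split(obs, obs$frame)
  times <- unname(vapply(byFrame, function(f) f$time_h[1], numeric(1)))
  raw <- unname(vapply(byFrame, nrow, integer(1)))
  o <- order(times)
  times <- times[o]; raw <- raw[o]
  i0 <- firstMitosisIndex(raw)
  if (is.na(i0)) stop("first mitosis not observed")
  newCountCurve(ids, times - times[i0], raw, cleanCounts(raw))
})

#' @rdname countCurve
setMethod("countCurve", "LineageTree", function(x, ...) {
  nd <- nodes(x)
  nRoots <- sum(is.na(nd$parent_id))
  if (nRoots != 1L) stop("first mitosis not observed")
  div <- sort(nd$division_time[!is.na(nd$division_time)])
  if (!length(div)) stop("first mitosis not observed")
  times <- c(nd$birth_time[is.na(nd$parent_id)], div)
  counts <- c(1, 1 + seq_along(div))
  keep <- !duplicated(times, fromLast = TRUE)  # simultaneous divisions collapse
  times <- times[keep]; counts <- counts[keep]
  t0 <- times[which(counts >= 2)[1]]
  newCountCurve(embryoId(x), times - t0, counts, counts)
})

intraStages <- c(2, 4, 8, 16, 32)
interBands <- list("3" = c(3, 3), "5-7" = c(5, 7), "9-15" = c(9, 15),
                   "17-31" = c(17, 31))

#' Intra- and inter-stage durations of a count curve
#'
#' Treats the cleaned curve as piecewise constant between frames. The intra
#' duration of stage s (2, 4, 8, 16, 32 cells) is the total time the count
#' equals s exactly; the inter duration of a band is the total time the
#' count lies inside it (3, 5-7, 9-15, 17-31 cells). Stages whose upper
#' bound the recording never passed are NA and flagged incomplete; on a
#' complete curve the intra durations of 2-16 plus all inter durations add
#' up to the time from first mitosis to first attainment of 32 cells.
#'
#' @param curve a \linkS4class{CountCurve}.
#' @return a \linkS4class{StageDurations}.
#' @examples
#' tr <- simulateLineage(simulationConfig(seed = 2), 1)
#' stageDurations(countCurve(tr))
#' @export
stageDurations <- function(curve) {
  times <- curveTimes(curve)
  cc <- cleanedCounts(curve)
  n <- length(times)
  seg <- if (n >= 2) diff(times) else numeric(0)
  cseg <- cc[-n]
  maxC <- max(cc)
  intra <- setNames(rep(0, length(intraStages)), as.character(intraStages))
  for (s in intraStages) {
    if (maxC <= s) { intra[as.character(s)] <- NA_real_; next }
    intra[as.character(s)] <- sum(seg[cseg == s])
  }
  inter <- setNames(rep(0, length(interBands)), names(interBands))
  for (b in names(interBands)) {
    hi <- interBands[[b]][2]
    if (maxC <= hi) { inter[b] <- NA_real_; next }
    lo <- interBands[[b]][1]
    inter[b] <- sum(seg[cseg >= lo & cseg <= hi])
  }
  incomplete <- c(names(intra)[is.na(intra)], names(inter)[is.na(inter)])
  new("StageDurations", intra = intra, inter = inter, incomplete = incomplete)
}

#' Per-blastomere division durations of one round
#'
#' Durations (division minus birth, hours) of every blastomere of the given
#' round: 2 values for the second duration (2-to-4-cell round), 4 for the
#' third (4-to-8), 8 for the fourth (8-to-16).
#'
#' @param tree a \linkS4class{LineageTree}.
#' @param roundIndex division round (1 = zygote).
#' @return numeric vector of durations in hours.
#' @export
divisionDurations <- function(tree, roundIndex) {
  nd <- nodes(tree)
  sel <- nd[nd$round_index == roundIndex, , drop = FALSE]
  if (!nrow(sel)) stop("no blastomeres of round ", roundIndex, " in the tree")
  und <- sel$node_id[is.na(sel$division_time)]
  if (length(und))
    stop("round ", roundIndex, " incomplete; undivided node(s): ",
         paste(und, collapse = ", "))
  sel$division_time - sel$birth_time
}

#' @rdname EmbryoSynchrony-accessors
#' @details \code{secondDiffNorm} applied to two durations returns their
#'   absolute difference divided by their mean (the normalized
#'   second-duration difference); applied to a
#'   \linkS4class{SynchronyProfile} it extracts the stored value.
setMethod("secondDiffNorm", "numeric", function(object) {
  if (length(object) != 2L) stop("expected exactly 2 second durations")
  if (any(object <= 0)) stop("durations must be positive")
  abs(object[1] - object[2]) / mean(object)
})

#' Coefficient of variation of division durations
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' within-embryo synchrony index when applied to third- or fourth-round
#' durations.
#'
#' @param durations numeric vector of at least 2 positive durations.
#' @return unitless CV.
#' @examples
#' durationCV(c(10, 11, 12, 19))  # 0.314
#' @export
durationCV <- function(durations) {
  if (length(durations) < 2L) stop("need at least 2 durations")
  if (any(durations <= 0)) stop("durations must be positive")
  sd(durations) / mean(durations)
}

#' Classify an embryo as synchrony high or low
#'
#' "high" when the third-round duration CV is at or above the cutoff
#' (boundary inclusive), "low" otherwise.
#'
#' @param thirdCV third-round duration CV (>= 0).
#' @param cutoff classification cutoff, default 0.15.
#' @return "high" or "low".
#' @export
classifySynchrony <- function(thirdCV, cutoff = 0.15) {
  if (any(thirdCV < 0)) stop("CV must be non-negative")
  ifelse(thirdCV >= cutoff, "high", "low")
}

#' Synchrony profile of one embryo
#'
#' Computes the normalized second-duration difference, the third- and
#' fourth-round duration CVs and the high/low class from a lineage tree.
#'
#' @param tree a \linkS4class{LineageTree} (round 4 complete).
#' @param cutoff classification cutoff on the third CV.
#' @return a \linkS4class{SynchronyProfile}.
#' @examples
#' tr <- simulateLineage(simulationConfig(roundCV = 0.2, seed = 4), 1)
#' synchronyProfile(tr)
#' @export
synchronyProfile <- function(tree, cutoff = 0.15) {
  if ("tracking_failure" %in% tree@flags)
    stop("embryo ", embryoId(tree), " is unanalyzable (tracking failure)")
  s2 <- secondDiffNorm(divisionDurations(tree, 2))
  cv3 <- durationCV(divisionDurations(tree, 3))
  cv4 <- durationCV(divisionDurations(tree, 4))
  new("SynchronyProfile", embryoId = embryoId(tree), secondDiffNorm = s2,
      thirdCV = cv3, fourthCV = cv4,
      synchronyClass = classifySynchrony(cv3, cutoff), cutoff = cutoff)
}
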