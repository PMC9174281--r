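## lineage linking: frame-to-frame nearest-neighbour assignment with a
## division hypothesis on count increases.

#' Link per-frame observations into a lineage tree
#'
#' Frames are matched by optimal one-to-one assignment on Euclidean distance
#' (Jonker-Volgenant). A count increase of +1 creates a division: the
#' unmatched new observation is paired with the nearest previous track,
#' whose matched and unmatched successors become the two daughters; the
#' division time is the midpoint of the two frames. Transient count
#' decreases (detection dropouts) are skipped; a decrease persisting more
#' than \code{maxMissingFrames} frames marks the embryo as unanalyzable
#' (flag \code{"tracking_failure"}).
#'
#' @param observations nucleus-observation data.frame of a single embryo,
#'   with at least 2 frames.
#' @param maxMissingFrames tolerated consecutive frames with missing
#'   detections.
#' @return a \linkS4class{LineageTree}; roots are the cells of the first
#'   frame (round_index 1 when the recording starts at the zygote).
#' @examples
#' cfg <- simulationConfig(seed = 5)
#' tr <- simulateLineage(cfg, 1)
#' obs <- simulateTrajectories(tr, cfg)
#' est <- linkTracks(obs)
#' est
#' @export
linkTracks <- function(observations, maxMissingFrames = 2L) {
  obs <- asObservations(observations)
  ids <- unique(obs$embryo_id)
  if (length(ids) != 1L)
    stop("linkTracks expects observations of a single embryo, got ",
         length(ids))
  frames <- split(obs, obs$frame)
  if (length(frames) < 2L) stop("need at least 2 frames")
  f1 <- frames[[1]]
  nodesDf <- data.frame(node_id = seq_len(nrow(f1)),
                        parent_id = NA_integer_,
                        round_index = 1L,
                        birth_time = f1$time_h[1],
                        division_time = NA_real_)
  trackNode <- seq_len(nrow(f1))            # node id of each active track
  trackPos <- as.matrix(f1[, c("x", "y", "z")])
  prevTime <- f1$time_h[1]
  missStreak <- 0L
  flags <- character()
  for (fi in seq_along(frames)[-1]) {
    cur <- frames[[fi]]
    curPos <- as.matrix(cur[, c("x", "y", "z")])
    tCur <- cur$time_h[1]
    nPrev <- nrow(trackPos); nCur <- nrow(curPos)
    if (nCur < nPrev) {
      missStreak <- missStreak + 1L
      if (missStreak > maxMissingFrames) {
        flags <- "tracking_failure"
        break
      }
      next
    }
    missStreak <- 0L
    pairs <- matchPoints(trackPos, curPos)
    succ <- rep(NA_integer_, nPrev)          # successor observation per track
    succ[pairs[, 1]] <- pairs[, 2]
    if (nCur > nPrev) {
      unmatched <- setdiff(seq_len(nCur), succ[!is.na(succ)])
      splitDone <- logical(nPrev)
      daughters <- vector("list", nPrev)
      tDiv <- (prevTime + tCur) / 2
      for (u in unmatched) {
        # division hypothesis: the parent sits at the midpoint of its two
        # daughters. Jointly choose the parent p and the sibling point c
        # (any currently assigned observation); claiming a point matched to
        # another track q re-routes q to p's former successor, so that swap
        # enters the cost.
        best <- list(cost = Inf, p = NA_integer_, c = NA_integer_)
        for (p in which(!splitDone & !is.na(succ))) {
          for (c_ in succ[!is.na(succ)]) {
            mid <- (curPos[c_, ] + curPos[u, ]) / 2
            cost <- sum((trackPos[p, ] - mid)^2)
            q <- which(succ == c_)
            if (q != p)
              cost <- cost + sum((trackPos[q, ] - curPos[succ[p], ])^2) -
                sum((trackPos[q, ] - curPos[c_, ])^2)
            if (cost < best$cost) best <- list(cost = cost, p = p, c = c_)
          }
        }
        p <- best$p
        q <- which(succ == best$c)
        if (q != p) succ[q] <- succ[p]       # q inherits p's old successor
        succ[p] <- NA_integer_
        splitDone[p] <- TRUE
        parentNode <- trackNode[p]
        pRow <- match(parentNode, nodesDf$node_id)
        nodesDf$division_time[pRow] <- tDiv
        kidIds <- max(nodesDf$node_id) + 1:2
        nodesDf <- rbind(nodesDf, data.frame(
          node_id = kidIds, parent_id = parentNode,
          round_index = nodesDf$round_index[pRow] + 1L,
          birth_time = tDiv, division_time = NA_real_))
        daughters[[p]] <- list(obs = c(best$c, u), nodes = kidIds)
      }
      # rebuild the active track set: survivors follow their successor,
      # split tracks are replaced by their two daughters
      keep <- which(!splitDone)
      newNode <- trackNode[keep]
      newPos <- curPos[succ[keep], , drop = FALSE]
      for (p in which(splitDone)) {
        newNode <- c(newNode, daughters[[p]]$nodes)
        newPos <- rbind(newPos, curPos[daughters[[p]]$obs, , drop = FALSE])
      }
      trackNode <- newNode
      trackPos <- newPos
    } else {
      trackPos[pairs[, 1], ] <- curPos[pairs[, 2], , drop = FALSE]
    }
    prevTime <- tCur
  }
  lineageTree(ids, nodesDf, flags)
}
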