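## synthetic embryo generator: lineages, confined trajectories, rendered
## volumes and outcome labels. Coordinates follow the package convention:
## isotropic units where 1 unit = dx, origin at the volume corner, so that
## z / (dz/dx) recovers the slice index.

# Seed stream: every stochastic stage derives its own 31-bit seed from the
# config seed, the embryo index and a stage salt, so stages are independently
# reproducible.
deriveSeed <- function(seed, index, salt) {
  as.integer((as.numeric(seed) * 7919 + index * 104729 + salt * 15485863) %%
               2147483647)
}

lognormalDurations <- function(n, meanDur, cv) {
  if (meanDur <= 0) stop("mean duration must be strictly positive")
  if (cv == 0) return(rep(meanDur, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(meanDur) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a blastomere lineage tree
#'
#' Grows a rooted binary tree through five division rounds (zygote to 32
#' terminal cells). Each blastomere of round r draws its duration from a
#' log-normal distribution with the round's mean and coefficient of
#' variation; children are born at the parent's division time.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param embryoIndex index of the embryo within the cohort (keys the seed).
#' @return a \linkS4class{LineageTree} with 63 nodes (32 terminal).
#' @examples
#' tr <- simulateLineage(simulationConfig(seed = 7), 1)
#' divisionDurations(tr, 3)
#' @export
simulateLineage <- function(config, embryoIndex = 1L) {
  validObject(config)
  set.seed(deriveSeed(config@seed, embryoIndex, 1L))
  nodes <- data.frame(node_id = 1L, parent_id = NA_integer_,
                      round_index = 1L, birth_time = 0,
                      division_time = NA_real_)
  nextId <- 2L
  for (r in 1:5) {
    idx <- which(nodes$round_index == r)
    dur <- lognormalDurations(length(idx), config@roundMeanDuration[r],
                              config@roundCV[r])
    nodes$division_time[idx] <- nodes$birth_time[idx] + dur
    for (k in seq_along(idx)) {
      i <- idx[k]
      kids <- data.frame(node_id = c(nextId, nextId + 1L),
                         parent_id = nodes$node_id[i],
                         round_index = r + 1L,
                         birth_time = nodes$division_time[i],
                         division_time = NA_real_)
      nodes <- rbind(nodes, kids)
      nextId <- nextId + 2L
    }
  }
  lineageTree(sprintf("sim%03d", embryoIndex), nodes)
}

reflectIntoSphere <- function(p, r) {
  nrm <- sqrt(sum(p^2))
  if (nrm > r) {
    p <- p * (2 * r - nrm) / nrm
    nrm <- sqrt(sum(p^2))
    if (nrm > r) p <- p * r / nrm
  }
  p
}

# excluded volume: nuclei are impenetrable spheres, so pairs closer than
# minSep are pushed apart symmetrically (a few relaxation sweeps), then
# re-confined to the embryo sphere
resolveOverlaps <- function(pos, idx, minSep, rIn, iters = 8L) {
  if (length(idx) < 2L) return(pos)
  for (it in seq_len(iters)) {
    moved <- FALSE
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        dv <- pos[j, ] - pos[i, ]
        d <- sqrt(sum(dv^2))
        if (d < minSep) {
          u <- if (d > 1e-9) dv / d else c(1, 0, 0)
          push <- (minSep - d) / 2
          pos[i, ] <- reflectIntoSphere(pos[i, ] - u * push, rIn)
          pos[j, ] <- reflectIntoSphere(pos[j, ] + u * push, rIn)
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  pos
}

#' Simulate confined nucleus trajectories for a lineage
#'
#' One observation per living blastomere per frame. Nuclei follow a Gaussian
#' random walk reflected at the embryo sphere; at division the two daughters
#' appear on a uniformly random axis through the parent centroid, at least
#' one nucleus diameter apart. Coordinates are emitted in isotropic units on
#' the rendering volume (see \code{\link{renderFrame}}).
#'
#' @param tree a \linkS4class{LineageTree}.
#' @param config the \linkS4class{SimulationConfig} used to build it.
#' @param nFrames optional frame count; default covers the last division plus
#'   two frames.
#' @return data.frame with columns embryo_id, frame, time_h, node_id, x, y, z.
#' @export
simulateTrajectories <- function(tree, config, nFrames = NULL) {
  validObject(tree)
  nd <- nodes(tree)
  set.seed(deriveSeed(config@seed, as.integer(sub("\\D+", "", tree@embryoId)) %||% 1L, 2L))
  dt <- config@frameInterval
  tEnd <- max(nd$division_time, na.rm = TRUE) + 2 * dt
  if (is.null(nFrames)) nFrames <- ceiling(tEnd / dt) + 1L
  rIn <- max(config@embryoRadius - config@nucleusRadius, config@nucleusRadius)
  sep <- 1.1 * 2 * config@nucleusRadius
  pos <- matrix(NA_real_, nrow = nrow(nd), ncol = 3)
  u0 <- runif(3, -1, 1)
  pos[1, ] <- reflectIntoSphere(u0 / max(sqrt(sum(u0^2)), 1) * rIn * 0.3, rIn)
  alive <- function(t) which(nd$birth_time <= t + 1e-9 &
                               (is.na(nd$division_time) | nd$division_time > t + 1e-9))
  out <- vector("list", nFrames)
  prevAlive <- integer()
  center <- config@volumeDim * config@voxelSpacing / 2
  dx <- config@voxelSpacing[1]
  for (f in seq_len(nFrames)) {
    t <- (f - 1L) * dt
    cur <- alive(t)
    newborn <- setdiff(cur, prevAlive)
    # place newborns pairwise at their parent's last position; the division
    # axis is drawn toward free space (best of a few random axes)
    for (i in newborn) {
      if (!is.na(pos[i, 1])) next
      par <- nd$parent_id[i]
      if (is.na(par)) { pos[i, ] <- c(0, 0, 0); next }
      pi_ <- match(par, nd$node_id)
      sib <- setdiff(which(nd$parent_id %in% par), i)
      others <- setdiff(cur, c(i, sib))
      others <- others[!is.na(pos[others, 1])]
      axes <- matrix(rnorm(24), 8, 3)
      axes <- axes / sqrt(rowSums(axes^2))
      score <- apply(axes, 1, function(ax) {
        pA <- pos[pi_, ] + ax * sep / 2
        pB <- pos[pi_, ] - ax * sep / 2
        if (!length(others)) return(1)
        op <- pos[others, , drop = FALSE]
        min(sqrt(rowSums(sweep(op, 2, pA)^2)),
            sqrt(rowSums(sweep(op, 2, pB)^2)))
      })
      ax <- axes[which.max(score), ]
      pos[i, ] <- reflectIntoSphere(pos[pi_, ] + ax * sep / 2, rIn)
      if (length(sib) && is.na(pos[sib[1], 1]))
        pos[sib[1], ] <- reflectIntoSphere(pos[pi_, ] - ax * sep / 2, rIn)
    }
    # diffusion step for cells already present
    for (i in setdiff(cur, newborn)) {
      if (f > 1L && config@motionStepSD > 0)
        pos[i, ] <- reflectIntoSphere(pos[i, ] + rnorm(3, 0, config@motionStepSD), rIn)
    }
    pos <- resolveOverlaps(pos, cur, 2 * config@nucleusRadius, rIn)
    out[[f]] <- data.frame(embryo_id = tree@embryoId, frame = f, time_h = t,
                           node_id = nd$node_id[cur],
                           x = (pos[cur, 1] + center[1]) / dx,
                           y = (pos[cur, 2] + center[2]) / dx,
                           z = (pos[cur, 3] + center[3]) / dx)
    prevAlive <- cur
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Render one volumetric frame from nucleus positions
#'
#' Sum of isotropic Gaussian intensity blobs (peak 1, width \code{psfSigma})
#' evaluated in physical coordinates and sampled on the anisotropic voxel
#' grid, multiplied by exponential depth attenuation, plus additive Gaussian
#' noise clipped at zero.
#'
#' @param observations data.frame with columns x, y, z in isotropic units on
#'   the volume (as produced by \code{\link{simulateTrajectories}}); may be
#'   empty.
#' @param config a \linkS4class{SimulationConfig}.
#' @param time frame time in hours (metadata).
#' @param frameIndex frame number (metadata).
#' @return a \linkS4class{VoxelGrid}.
#' @export
renderFrame <- function(observations, config, time = 0, frameIndex = 1L) {
  d <- config@volumeDim
  sp <- config@voxelSpacing
  vol <- array(0, dim = d)
  sig <- config@psfSigma
  if (nrow(observations)) {
    dx <- sp[1]
    for (i in seq_len(nrow(observations))) {
      cx <- observations$x[i] * dx              # physical um
      cy <- observations$y[i] * dx
      cz <- observations$z[i] * dx
      ix <- seq(max(1, floor((cx - 4 * sig) / sp[1]) + 1),
                min(d[1], ceiling((cx + 4 * sig) / sp[1]) + 1))
      iy <- seq(max(1, floor((cy - 4 * sig) / sp[2]) + 1),
                min(d[2], ceiling((cy + 4 * sig) / sp[2]) + 1))
      iz <- seq(max(1, floor((cz - 4 * sig) / sp[3]) + 1),
                min(d[3], ceiling((cz + 4 * sig) / sp[3]) + 1))
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-((ix - 1) * sp[1] - cx)^2 / (2 * sig^2))
      gy <- exp(-((iy - 1) * sp[2] - cy)^2 / (2 * sig^2))
      gz <- exp(-((iz - 1) * sp[3] - cz)^2 / (2 * sig^2))
      blob <- outer(outer(gx, gy), gz)
      vol[ix, iy, iz] <- vol[ix, iy, iz] + blob
    }
  }
  if (config@zAttenuation > 0) {
    att <- exp(-config@zAttenuation * (seq_len(d[3]) - 1) * sp[3])
    vol <- sweep(vol, 3, att, `*`)
  }
  if (config@noiseSD > 0)
    vol <- vol + array(rnorm(prod(d), 0, config@noiseSD), dim = d)
  vol[vol < 0] <- 0
  voxelGrid(vol, spacing = sp, time = time, frameIndex = frameIndex)
}

#' Outcome labels from the synchrony index
#'
#' Assigns a born/abort label with abort probability following a logistic
#' curve in the third-round CV, calibrated so that embryos at or above the
#' 0.15 synchrony cutoff have high abort odds.
#'
#' @param thirdCV numeric vector of per-embryo third-round duration CVs.
#' @param center CV at which abort probability is 0.5.
#' @param slope logistic slope (per CV unit).
#' @return character vector "born"/"abort" (draws from the current RNG).
#' @export
assignOutcome <- function(thirdCV, center = 0.10, slope = 40) {
  p <- stats::plogis(slope * (thirdCV - center))
  ifelse(stats::runif(length(thirdCV)) < p, "abort", "born")
}

#' True per-round duration CV of a lineage
#'
#' Sample CV (n - 1 standard deviation over mean) of the durations of all
#' round-\code{roundIndex} blastomeres, recomputed from the tree.
#'
#' @param tree a \linkS4class{LineageTree}.
#' @param roundIndex division round (2 = second duration, 3 = third, ...).
#' @return unitless CV.
#' @export
trueRoundCV <- function(tree, roundIndex) {
  durationCV(divisionDurations(tree, roundIndex))
}

#' Simulate a full synthetic cohort
#'
#' Generates lineages, trajectories and outcome labels for
#' \code{nEmbryos(config)} embryos. The ground-truth third-round CV of each
#' embryo is the sample CV recomputed from its lineage; outcomes follow the
#' logistic rule of \code{\link{assignOutcome}}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param thirdCVGrid optional vector of third-round CV values cycled over
#'   embryos (overrides \code{roundCV[3]} per embryo).
#' @param outcomeCenter,outcomeSlope parameters of the outcome rule.
#' @return list with elements \code{lineages} (list of
#'   \linkS4class{LineageTree}), \code{observations} (combined coordinate
#'   table), \code{truth} (per-embryo data.frame: embryo_id, true second
#'   difference, true third/fourth CV, outcome) and \code{config}.
#' @export
simulateCohort <- function(config, thirdCVGrid = NULL,
                           outcomeCenter = 0.10, outcomeSlope = 40) {
  validObject(config)
  n <- config@nEmbryos
  lineages <- vector("list", n)
  obs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    if (!is.null(thirdCVGrid))
      cfg@roundCV[3] <- thirdCVGrid[((i - 1L) %% length(thirdCVGrid)) + 1L]
    tr <- simulateLineage(cfg, i)
    lineages[[i]] <- tr
    obs[[i]] <- simulateTrajectories(tr, cfg)
    truth[[i]] <- data.frame(
      embryo_id = tr@embryoId,
      true_second_diff = secondDiffNorm(divisionDurations(tr, 2)),
      true_third_cv = trueRoundCV(tr, 3),
      true_fourth_cv = trueRoundCV(tr, 4))
  }
  truth <- do.call(rbind, truth)
  set.seed(deriveSeed(config@seed, 0L, 3L))
  truth$outcome <- assignOutcome(truth$true_third_cv, outcomeCenter, outcomeSlope)
  list(config = config, lineages = lineages,
       observations = do.call(rbind, obs), truth = truth)
}
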