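## nucleus detection: the volumetric processing chain that turns one 3D
## frame into nucleus centroids. Stages: signal amplification (background
## subtraction, clip-limited equalization, median denoising), z-bias
## correction, Otsu thresholding with small-component removal, iterative
## watershed subdivision of oversize submasks, centroid measurement.

#' Amplify the nuclear signal of a frame
#'
#' Noise is removed by a 3D median filter of half-width
#' \code{denoiseRadius}; background is estimated by grey morphological
#' opening (minimum then maximum filter with a cubic element of half-width
#' \code{backgroundRadius}, the rolling-ball analogue) and subtracted;
#' finally clip-limited global histogram equalization amplifies the nuclear
#' signal. Denoising precedes equalization because any histogram-based
#' stretch applied to raw shot noise brightens the background and defeats
#' the downstream automatic threshold. All-zero frames pass through
#' unchanged.
#'
#' @param frame a \linkS4class{VoxelGrid}.
#' @param params a \linkS4class{DetectionParams}.
#' @return the preprocessed \linkS4class{VoxelGrid}.
#' @export
preprocessFrame <- function(frame, params = detectionParams()) {
  v <- intensities(frame)
  if (max(v) == 0) return(frame)
  d <- dim(v)
  if (params@denoiseRadius >= 1L)
    v <- cpp_medfilt3(v, d, params@denoiseRadius)
  bg <- cpp_minmaxfilt3(cpp_minmaxfilt3(v, d, params@backgroundRadius, FALSE),
                        d, params@backgroundRadius, TRUE)
  v <- pmax(v - bg, 0)
  dim(v) <- d
  if (params@equalize && max(v) > 0)
    v <- equalizeClipped(v, params@clipLimit)
  v[v < 0] <- 0
  voxelGrid(v, spacing = spacing(frame), time = frame@time,
            frameIndex = frame@frameIndex)
}

#' Correct the intensity bias along the z axis
#'
#' Depth-dependent signal loss is removed by rescaling each z slice so that
#' its foreground quantile matches the brightest slice. Foreground voxels
#' are those above both \code{floorFrac} of the volume maximum and a robust
#' noise ceiling (median + 8 MAD of the positive voxels), so slices holding
#' only background noise are never rescaled; slices with fewer than
#' \code{minVoxels} foreground voxels are left untouched.
#'
#' @param frame a \linkS4class{VoxelGrid}.
#' @param prob foreground quantile equalized across slices.
#' @param floorFrac foreground floor as a fraction of the volume maximum.
#' @param minVoxels minimum foreground voxels for a slice to be rescaled.
#' @param maxScale cap on the per-slice scale factor.
#' @return the corrected \linkS4class{VoxelGrid}.
#' @export
correctZBias <- function(frame, prob = 0.99, floorFrac = 0.15,
                         minVoxels = 10L, maxScale = 20) {
  v <- intensities(frame)
  gmax <- max(v)
  if (gmax == 0) return(frame)
  pos <- v[v > 0]
  noiseCeil <- median(pos) + 8 * stats::mad(pos)
  floor_ <- max(floorFrac * gmax, min(noiseCeil, 0.9 * gmax))
  nz <- dim(v)[3]
  q <- rep(NA_real_, nz)
  for (k in seq_len(nz)) {
    sl <- v[, , k]
    fg <- sl[sl > floor_]
    if (length(fg) >= minVoxels) q[k] <- quantile(fg, prob, names = FALSE)
  }
  if (all(is.na(q))) return(frame)
  ref <- max(q, na.rm = TRUE)
  for (k in seq_len(nz))
    if (!is.na(q[k]) && q[k] > 0)
      v[, , k] <- v[, , k] * min(ref / q[k], maxScale)
  voxelGrid(v, spacing = spacing(frame), time = frame@time,
            frameIndex = frame@frameIndex)
}

#' Binarize a preprocessed frame
#'
#' Foreground mask from a global Otsu threshold. Nuclei occupy well under a
#' percent of the volume, and on such unbalanced histograms a single Otsu
#' split lands inside the background mode; the threshold is therefore
#' applied recursively (re-estimated on the above-threshold voxels) until
#' the foreground fraction falls below 1% — nuclei never occupy more than
#' that, and at such occupancy background speckle cannot form 26-connected
#' clusters anywhere near the component-size floor. Components smaller than
#' \code{minComponentSize} voxels are dropped. An empty result is valid.
#'
#' @param frame a \linkS4class{VoxelGrid} (preprocessed).
#' @param params a \linkS4class{DetectionParams}.
#' @return logical 3D array.
#' @export
binarizeFrame <- function(frame, params = detectionParams()) {
  v <- intensities(frame)
  d <- dim(v)
  if (max(v) == min(v)) return(array(FALSE, dim = d))
  thr <- otsuThreshold(v)
  for (i in 1:6) {
    if (mean(v > thr) < 0.01) break
    sel <- v[v > thr]
    if (!length(sel) || diff(range(sel)) == 0) break
    nt <- otsuThreshold(sel)
    if (!any(v > nt)) break
    thr <- nt
  }
  # the z-bias step equalizes nucleus peaks across the volume, so any real
  # nucleus reaches a fixed fraction of the volume maximum while residual
  # noise stays far below it; a relative floor keeps rare large noise
  # clusters out of the mask
  thr <- max(thr, 0.35 * max(v))
  if (!any(v > thr)) return(array(FALSE, dim = d))
  mask <- v > thr
  lab <- cpp_label3d(mask, d)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < params@minComponentSize)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  dim(mask) <- d
  mask
}

# isotropic-unit coordinates (1 unit = dx) of the voxels of one label,
# 0-based indices
labelCoordsIso <- function(lab, id, spacing) {
  w <- which(lab == id)
  d <- dim(lab)
  z <- (w - 1) %/% (d[1] * d[2])
  rem <- (w - 1) %% (d[1] * d[2])
  y <- rem %/% d[1]
  x <- rem %% d[1]
  cbind(x, y * spacing[2] / spacing[1], z * spacing[3] / spacing[1])
}

# principal-axis extents (length >= width) of a voxel point cloud
principalExtents <- function(pts) {
  if (nrow(pts) == 1L) return(c(length = 1, width = 1))
  pc <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)$vectors
  proj <- pc %*% ev
  ext <- apply(proj, 2, function(p) diff(range(p)) + 1)
  c(length = ext[1], width = ext[2])
}

# greedy selection of local EDT maxima at least minSep apart (isotropic
# units); maxima below half the component's peak distance are noise spurs on
# a ragged boundary, not nucleus centers, and are ignored
selectMarkers <- function(edt, d, spacing, minSep) {
  mx <- cpp_minmaxfilt3(edt, d, 1L, TRUE)
  cand <- which(edt >= 0.5 * max(edt) & edt >= mx - 1e-12)
  if (!length(cand)) return(NULL)
  ord <- cand[order(edt[cand], decreasing = TRUE)]
  z <- (ord - 1) %/% (d[1] * d[2])
  rem <- (ord - 1) %% (d[1] * d[2])
  pts <- cbind(rem %% d[1],
               (rem %/% d[1]) * spacing[2] / spacing[1],
               z * spacing[3] / spacing[1])
  keep <- integer()
  for (i in seq_along(ord)) {
    if (!length(keep)) { keep <- i; next }
    dd <- sqrt(rowSums((pts[keep, , drop = FALSE] -
                          matrix(pts[i, ], length(keep), 3, byrow = TRUE))^2))
    if (all(dd >= minSep)) keep <- c(keep, i)
  }
  ord[keep]
}

#' Subdivide merged nuclei by iterative watershed
#'
#' Labels the mask (26-connectivity) and repeatedly measures each submask's
#' length and width (extents along its first two principal axes, isotropic
#' units). Submasks exceeding \code{subdivisionFactor} times the median
#' length or median width are re-split by a marker-based watershed on the
#' anisotropy-aware Euclidean distance transform, with markers at distance
#' maxima separated by at least half the median width. The loop stops when
#' no candidate remains or after \code{maxSubdivisionIters} iterations.
#'
#' @param mask logical 3D array from \code{\link{binarizeFrame}}.
#' @param params a \linkS4class{DetectionParams}.
#' @param spacing voxel pitch (dx, dy, dz), micrometres.
#' @return integer 3D array of nucleus labels (0 = background).
#' @export
subdivideMask <- function(mask, params = detectionParams(),
                          spacing = c(0.8, 0.8, 2.0)) {
  d <- dim(mask)
  lab <- cpp_label3d(mask, d)
  if (max(lab) < 1L) return(lab)
  frozen <- logical(max(lab))
  isoSp <- spacing / spacing[1]
  for (iter in seq_len(params@maxSubdivisionIters)) {
    ids <- sort(unique(lab[lab > 0]))
    ext <- t(vapply(ids, function(id)
      principalExtents(labelCoordsIso(lab, id, spacing)), numeric(2)))
    medL <- median(ext[, 1]); medW <- median(ext[, 2])
    oversized <- ext[, 1] > params@subdivisionFactor * medL |
      ext[, 2] > params@subdivisionFactor * medW
    cand <- ids[oversized & !frozen[ids]]
    if (!length(cand)) break
    minSep <- max(medW / 2, 1)
    nextLab <- max(lab) + 1L
    for (id in cand) {
      sub <- lab == id
      edt <- cpp_edt3(sub, d, isoSp)
      mk <- selectMarkers(edt, d, spacing, minSep)
      if (length(mk) < 2L) { frozen[id] <- TRUE; next }
      markers <- integer(length(lab)); dim(markers) <- d
      markers[mk] <- seq_along(mk)
      ws <- cpp_watershed3(-edt, markers, sub, d)
      lab[sub] <- nextLab + ws[sub] - 1L
      nextLab <- nextLab + length(mk)
      frozen <- c(frozen, rep(FALSE, max(0L, nextLab - 1L - length(frozen))))
    }
    # compact labels, carrying frozen flags
    ids <- sort(unique(lab[lab > 0]))
    map <- integer(max(ids))
    map[ids] <- seq_along(ids)
    frozen <- frozen[ids]
    lab[lab > 0] <- map[lab[lab > 0]]
    dim(lab) <- d
  }
  # a nucleus cannot be smaller than the component-size floor; drop
  # fragments the watershed may have carved off a noisy boundary
  sizes <- tabulate(lab[lab > 0], nbins = max(lab, 1L))
  small <- which(sizes > 0 & sizes < params@minComponentSize)
  if (length(small)) {
    lab[lab %in% small] <- 0L
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids)) {
      map <- integer(max(ids))
      map[ids] <- seq_along(ids)
      lab[lab > 0] <- map[lab[lab > 0]]
    }
    dim(lab) <- d
  }
  lab
}

#' Measure nucleus centroids and volumes
#'
#' One observation per label: the unweighted voxel centroid in isotropic
#' units, 0-based, with z pre-scaled by dz/dx (2.5 at the default spacing)
#' so that dividing the reported z by dz/dx recovers the slice index; volume
#' is the voxel count.
#'
#' @param labels integer 3D label array.
#' @param frame the \linkS4class{VoxelGrid} the labels came from.
#' @param embryoId embryo identifier for the output table.
#' @return nucleus-observation data.frame (embryo_id, frame, time_h, x, y, z,
#'   volume).
#' @export
measureCentroids <- function(labels, frame, embryoId = "embryo") {
  sp <- spacing(frame)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    return(asObservations(data.frame(embryo_id = character(), frame = integer(),
                                     time_h = numeric(), x = numeric(),
                                     y = numeric(), z = numeric(),
                                     volume = numeric())))
  }
  rows <- lapply(ids, function(id) {
    pts <- labelCoordsIso(labels, id, sp)
    data.frame(embryo_id = embryoId, frame = frame@frameIndex,
               time_h = frame@time, x = mean(pts[, 1]), y = mean(pts[, 2]),
               z = mean(pts[, 3]), volume = nrow(pts))
  })
  asObservations(do.call(rbind, rows))
}

#' Detect nuclei in one volumetric frame
#'
#' Composition of the full chain: preprocess, z-bias correction, Otsu
#' binarization with small-component removal, iterative watershed
#' subdivision, centroid measurement. Deterministic for fixed input and
#' parameters.
#'
#' @param frame a \linkS4class{VoxelGrid}.
#' @param params a \linkS4class{DetectionParams}.
#' @param embryoId embryo identifier.
#' @param verbose log per-stage object counts.
#' @return nucleus-observation data.frame.
#' @examples
#' cfg <- simulationConfig(seed = 3, volumeDim = c(64L, 64L, 32L))
#' obs <- data.frame(x = 32, y = 32, z = 12.8)  # one nucleus at slice 12.8
#' vg <- renderFrame(obs, cfg)
#' detectFrame(vg, embryoId = "demo")
#' @export
detectFrame <- function(frame, params = detectionParams(),
                        embryoId = "embryo", verbose = FALSE) {
  pre <- preprocessFrame(frame, params)
  zc <- correctZBias(pre)
  mask <- binarizeFrame(zc, params)
  if (verbose)
    message("binarize: ", max(cpp_label3d(mask, dim(mask))), " component(s)")
  lab <- subdivideMask(mask, params, spacing(frame))
  if (verbose) message("subdivide: ", max(lab), " label(s)")
  measureCentroids(lab, frame, embryoId)
}

#' Apply manual corrections to detected observations
#'
#' Replays a correction table (add / remove / move) against an observation
#' table, the programmatic equivalent of curating automatic detections
#' against a volume rendering. Edits are applied in row order; every edit is
#' recorded in the audit log attached as attribute \code{"audit"}.
#'
#' @param observations nucleus-observation data.frame; rows gain an
#'   \code{obs_id} (row number) if absent.
#' @param edits data.frame with columns \code{action} ("add", "remove",
#'   "move"), \code{obs_id} (for remove/move), \code{embryo_id},
#'   \code{frame}, \code{time_h}, \code{x}, \code{y}, \code{z} (for
#'   add/move).
#' @return corrected observation table with an \code{"audit"} attribute.
#' @export
applyManualCorrections <- function(observations, edits) {
  obs <- observations
  if (!"obs_id" %in% names(obs)) obs$obs_id <- seq_len(nrow(obs))
  audit <- character()
  if (nrow(edits) == 0) {
    attr(obs, "audit") <- audit
    return(obs)
  }
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$action == "add") {
      newRow <- data.frame(embryo_id = e$embryo_id, frame = e$frame,
                           time_h = e$time_h, x = e$x, y = e$y, z = e$z,
                           volume = NA_real_,
                           obs_id = max(obs$obs_id, 0L) + 1L)
      obs <- rbind(obs, newRow)
      audit <- c(audit, sprintf("add obs %d at frame %d", newRow$obs_id, e$frame))
    } else if (e$action %in% c("remove", "move")) {
      j <- which(obs$obs_id == e$obs_id)
      if (length(j) != 1L)
        stop("edit row ", i, ": observation id ", e$obs_id, " not found")
      if (e$action == "remove") {
        obs <- obs[-j, ]
        audit <- c(audit, sprintf("remove obs %d", e$obs_id))
      } else {
        obs$x[j] <- e$x; obs$y[j] <- e$y; obs$z[j] <- e$z
        audit <- c(audit, sprintf("move obs %d", e$obs_id))
      }
    } else stop("unknown action: ", e$action)
  }
  attr(obs, "audit") <- audit
  obs
}
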