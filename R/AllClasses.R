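#' @import methods
#' @importFrom stats median quantile rnorm runif rlnorm sd setNames aggregate
#' @useDynLib EmbryoSynchrony, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---- SimulationConfig -------------------------------------------------------

#' Simulation settings for the synthetic embryo generator
#'
#' Holds every parameter of the synthetic cohort: lineage timing (per-round
#' mean blastomere duration and coefficient of variation), geometry (embryo
#' and nucleus radius), nucleus motion, imaging model (PSF width, noise,
#' depth attenuation, anisotropic voxel spacing) and the random seed.
#'
#' Division rounds are numbered from the zygote: round 1 is the zygote
#' (1 to 2 cells), round 2 the 2-cell blastomeres (2 to 4), round 3 the
#' 4-cell blastomeres (4 to 8, the "third duration" of the synchrony index),
#' round 4 the 8-cell blastomeres and round 5 the 16-cell blastomeres.
#'
#' @slot nEmbryos number of embryos in the cohort.
#' @slot roundMeanDuration mean blastomere duration (hours) per round, length 5.
#' @slot roundCV within-embryo coefficient of variation of durations per round.
#' @slot embryoRadius radius of the confining sphere, micrometres.
#' @slot nucleusRadius nominal nucleus radius, micrometres.
#' @slot motionStepSD per-frame random-walk step standard deviation, micrometres.
#' @slot frameInterval time between frames, hours (default 1/6 h = 10 min).
#' @slot psfSigma isotropic Gaussian blob width used in rendering, micrometres.
#' @slot noiseSD additive Gaussian noise standard deviation, intensity units
#'   (nucleus peak intensity is 1).
#' @slot zAttenuation exponential intensity attenuation per micrometre of depth.
#' @slot voxelSpacing voxel pitch (dx, dy, dz) in micrometres.
#' @slot volumeDim rendered volume size (nx, ny, nz) in voxels.
#' @slot seed integer seed controlling all randomness.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nEmbryos = "integer",
  roundMeanDuration = "numeric",
  roundCV = "numeric",
  embryoRadius = "numeric",
  nucleusRadius = "numeric",
  motionStepSD = "numeric",
  frameInterval = "numeric",
  psfSigma = "numeric",
  noiseSD = "numeric",
  zAttenuation = "numeric",
  voxelSpacing = "numeric",
  volumeDim = "integer",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@roundMeanDuration) != 5L || any(object@roundMeanDuration <= 0))
    msg <- c(msg, "roundMeanDuration must be 5 strictly positive values")
  if (length(object@roundCV) != 5L || any(object@roundCV < 0))
    msg <- c(msg, "roundCV must be 5 non-negative values")
  if (object@embryoRadius <= 0 || object@nucleusRadius <= 0)
    msg <- c(msg, "radii must be strictly positive")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@motionStepSD < 0) msg <- c(msg, "motionStepSD must be >= 0")
  if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be > 0")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@zAttenuation < 0) msg <- c(msg, "zAttenuation must be >= 0")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be 3 strictly positive values")
  if (length(object@volumeDim) != 3L || any(object@volumeDim < 4L))
    msg <- c(msg, "volumeDim must be 3 integers >= 4")
  if (object@nEmbryos < 1L) msg <- c(msg, "nEmbryos must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a SimulationConfig
#'
#' Defaults describe a mouse preimplantation cohort imaged at 10-minute
#' intervals with 0.8 x 0.8 x 2.0 micrometre voxels: first cleavage round about
#' 18 h, later rounds about 12 h, low baseline asynchrony (CV 0.05), nuclei of
#' radius 4 um confined to a 30 um embryo sphere.
#'
#' @param nEmbryos cohort size.
#' @param roundMeanDuration per-round mean duration in hours (length 5).
#' @param roundCV per-round duration CV (length 5, or a scalar recycled to the
#'   division rounds 2-5 with round 1 kept tight).
#' @param embryoRadius,nucleusRadius geometry in micrometres.
#' @param motionStepSD random-walk step SD per frame, micrometres.
#' @param frameInterval hours between frames.
#' @param psfSigma,noiseSD,zAttenuation imaging model parameters.
#' @param voxelSpacing voxel pitch (dx, dy, dz), micrometres.
#' @param volumeDim rendered volume size (nx, ny, nz), voxels.
#' @param seed integer random seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nEmbryos = 2, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nEmbryos = 10L,
                             roundMeanDuration = c(18, 12, 12, 12, 12),
                             roundCV = c(0.02, 0.05, 0.05, 0.05, 0.05),
                             embryoRadius = 30,
                             nucleusRadius = 4,
                             motionStepSD = 0.5,
                             frameInterval = 1 / 6,
                             psfSigma = 2,
                             noiseSD = 0.05,
                             zAttenuation = 0.01,
                             voxelSpacing = c(0.8, 0.8, 2.0),
                             volumeDim = c(128L, 128L, 64L),
                             seed = 1L) {
  if (length(roundCV) == 1L) roundCV <- c(min(roundCV, 0.02), rep(roundCV, 4L))
  new("SimulationConfig",
      nEmbryos = as.integer(nEmbryos),
      roundMeanDuration = as.numeric(roundMeanDuration),
      roundCV = as.numeric(roundCV),
      embryoRadius = as.numeric(embryoRadius),
      nucleusRadius = as.numeric(nucleusRadius),
      motionStepSD = as.numeric(motionStepSD),
      frameInterval = as.numeric(frameInterval),
      psfSigma = as.numeric(psfSigma),
      noiseSD = as.numeric(noiseSD),
      zAttenuation = as.numeric(zAttenuation),
      voxelSpacing = as.numeric(voxelSpacing),
      volumeDim = as.integer(volumeDim),
      seed = as.integer(seed))
}

## ---- VoxelGrid --------------------------------------------------------------

#' One 3D intensity volume at one time point
#'
#' @slot intensities non-negative 3D array with dim (nx, ny, nz); x is the
#'   fastest axis, z the slice axis.
#' @slot spacing voxel pitch (dx, dy, dz) in micrometres.
#' @slot time acquisition time in hours.
#' @slot frameIndex integer frame number (1-based).
#' @exportClass VoxelGrid
setClass("VoxelGrid", representation(
  intensities = "array",
  spacing = "numeric",
  time = "numeric",
  frameIndex = "integer"
))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  if (any(!is.finite(object@intensities)) || any(object@intensities < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(msg)) msg else TRUE
})

#' Create a VoxelGrid
#'
#' @param intensities 3D array, dim (nx, ny, nz).
#' @param spacing voxel pitch (dx, dy, dz) in micrometres.
#' @param time acquisition time, hours.
#' @param frameIndex frame number.
#' @return a \linkS4class{VoxelGrid}.
#' @export
voxelGrid <- function(intensities, spacing = c(0.8, 0.8, 2.0), time = 0,
                      frameIndex = 1L) {
  new("VoxelGrid", intensities = intensities, spacing = as.numeric(spacing),
      time = as.numeric(time), frameIndex = as.integer(frameIndex))
}

## ---- DetectionParams --------------------------------------------------------

#' Parameters of the nucleus-detection chain
#'
#' @slot backgroundRadius half-width (voxels) of the grey-opening structuring
#'   element used as the rolling-ball background estimate.
#' @slot equalize logical; apply clip-limited global histogram equalization.
#' @slot clipLimit histogram clip factor (multiples of the uniform bin count).
#' @slot denoiseRadius half-width (voxels) of the 3D median filter.
#' @slot minComponentSize minimum connected-component size kept, voxels.
#' @slot subdivisionFactor multiplier on the median length/width above which a
#'   submask is re-split by watershed.
#' @slot maxSubdivisionIters cap on subdivision iterations.
#' @exportClass DetectionParams
setClass("DetectionParams", representation(
  backgroundRadius = "integer",
  equalize = "logical",
  clipLimit = "numeric",
  denoiseRadius = "integer",
  minComponentSize = "integer",
  subdivisionFactor = "numeric",
  maxSubdivisionIters = "integer"
))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@backgroundRadius < 1L) msg <- c(msg, "backgroundRadius must be >= 1")
  if (object@denoiseRadius < 0L) msg <- c(msg, "denoiseRadius must be >= 0")
  if (object@minComponentSize < 1L) msg <- c(msg, "minComponentSize must be >= 1")
  if (object@subdivisionFactor <= 0) msg <- c(msg, "subdivisionFactor must be > 0")
  if (object@maxSubdivisionIters < 1L) msg <- c(msg, "maxSubdivisionIters must be >= 1")
  if (object@clipLimit <= 1) msg <- c(msg, "clipLimit must be > 1")
  if (length(msg)) msg else TRUE
})

#' Create DetectionParams
#'
#' @param backgroundRadius rolling-ball (grey opening) half-width, voxels.
#' @param equalize apply clip-limited histogram equalization.
#' @param clipLimit equalization clip factor.
#' @param denoiseRadius 3D median-filter half-width, voxels.
#' @param minComponentSize smallest component kept, voxels.
#' @param subdivisionFactor oversize multiplier on median length/width.
#' @param maxSubdivisionIters iteration cap of the subdivision loop.
#' @return a validated \linkS4class{DetectionParams}.
#' @export
detectionParams <- function(backgroundRadius = 12L, equalize = FALSE,
                            clipLimit = 4, denoiseRadius = 1L,
                            minComponentSize = 64L, subdivisionFactor = 1.5,
                            maxSubdivisionIters = 10L) {
  new("DetectionParams",
      backgroundRadius = as.integer(backgroundRadius),
      equalize = as.logical(equalize),
      clipLimit = as.numeric(clipLimit),
      denoiseRadius = as.integer(denoiseRadius),
      minComponentSize = as.integer(minComponentSize),
      subdivisionFactor = as.numeric(subdivisionFactor),
      maxSubdivisionIters = as.integer(maxSubdivisionIters))
}

## ---- LineageTree ------------------------------------------------------------

#' Blastomere genealogy of one embryo
#'
#' Nodes form a rooted binary tree; a node either has no division time
#' (still alive at the end of the recording) or exactly two children whose
#' birth time equals the parent's division time.
#'
#' @slot embryoId embryo identifier.
#' @slot nodes data.frame with columns node_id, parent_id (NA for the root),
#'   round_index (1 = zygote), birth_time, division_time (NA if undivided);
#'   times in hours.
#' @slot flags character vector of quality flags (e.g. "tracking_failure").
#' @exportClass LineageTree
setClass("LineageTree", representation(
  embryoId = "character",
  nodes = "data.frame",
  flags = "character"
))

setValidity("LineageTree", function(object) {
  nd <- object@nodes
  req <- c("node_id", "parent_id", "round_index", "birth_time", "division_time")
  if (!all(req %in% names(nd)))
    return(paste("nodes must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(nd$node_id)) return("node_id must be unique")
  div <- nd[!is.na(nd$division_time), , drop = FALSE]
  if (nrow(div)) {
    if (any(div$division_time <= div$birth_time))
      return("division_time must exceed birth_time")
    kids <- table(factor(nd$parent_id[!is.na(nd$parent_id)],
                         levels = nd$node_id))
    if (any(kids[as.character(div$node_id)] != 2L))
      return("every divided node must have exactly 2 children")
    idx <- match(nd$parent_id, nd$node_id)
    ok <- is.na(nd$parent_id) |
      abs(nd$birth_time - nd$division_time[idx]) < 1e-9
    if (!all(ok, na.rm = TRUE))
      return("child birth_time must equal parent division_time")
  }
  TRUE
})

#' Create a LineageTree
#' @param embryoId embryo identifier.
#' @param nodes node table (see \linkS4class{LineageTree}).
#' @param flags optional quality flags.
#' @return a validated \linkS4class{LineageTree}.
#' @export
lineageTree <- function(embryoId, nodes, flags = character()) {
  new("LineageTree", embryoId = as.character(embryoId), nodes = nodes,
      flags = flags)
}

## ---- CountCurve -------------------------------------------------------------

#' Cell-count curve aligned to first mitosis
#'
#' @slot embryoId embryo identifier.
#' @slot times hours relative to first mitosis (t = 0 is the first persistent
#'   1-to-2 transition).
#' @slot rawCounts detected counts per frame.
#' @slot cleanedCounts monotone cleaned counts (running maximum followed by a
#'   3-point median).
#' @exportClass CountCurve
setClass("CountCurve", representation(
  embryoId = "character",
  times = "numeric",
  rawCounts = "numeric",
  cleanedCounts = "numeric"
))

setValidity("CountCurve", function(object) {
  if (length(object@times) != length(object@rawCounts) ||
      length(object@times) != length(object@cleanedCounts))
    return("times, rawCounts and cleanedCounts must have equal length")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (any(diff(object@cleanedCounts) < 0))
    return("cleanedCounts must be monotone non-decreasing")
  TRUE
})

## ---- StageDurations ---------------------------------------------------------

#' Intra- and inter-stage durations of a cleaned count curve
#'
#' Intra-stage: time spent at exactly 2, 4, 8, 16 or 32 cells. Inter-stage:
#' time spent strictly inside the bands 3, 5-7, 9-15 and 17-31 cells.
#' Stages the recording never completed are NA and listed in
#' \code{incomplete}.
#'
#' @slot intra named numeric, hours, names "2","4","8","16","32".
#' @slot inter named numeric, hours, names "3","5-7","9-15","17-31".
#' @slot incomplete names of stages not completed by the curve.
#' @exportClass StageDurations
setClass("StageDurations", representation(
  intra = "numeric",
  inter = "numeric",
  incomplete = "character"
))

## ---- SynchronyProfile -------------------------------------------------------

#' Per-embryo division-synchrony statistics
#'
#' @slot embryoId embryo identifier.
#' @slot secondDiffNorm absolute second-duration difference normalized by the
#'   mean second duration.
#' @slot thirdCV coefficient of variation of the four third-round durations
#'   (the synchrony index).
#' @slot fourthCV coefficient of variation of the eight fourth-round durations.
#' @slot synchronyClass "high" (thirdCV >= cutoff) or "low".
#' @slot cutoff classification cutoff used (default 0.15).
#' @exportClass SynchronyProfile
setClass("SynchronyProfile", representation(
  embryoId = "character",
  secondDiffNorm = "numeric",
  thirdCV = "numeric",
  fourthCV = "numeric",
  synchronyClass = "character",
  cutoff = "numeric"
))

setValidity("SynchronyProfile", function(object) {
  msg <- character()
  if (!object@synchronyClass %in% c("high", "low"))
    msg <- c(msg, "synchronyClass must be 'high' or 'low'")
  st <- c(object@secondDiffNorm, object@thirdCV, object@fourthCV)
  if (any(!is.na(st) & st < 0)) msg <- c(msg, "statistics must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---- RocSummary -------------------------------------------------------------

#' ROC cutoff sweep
#'
#' Positive class is "abort"; a score is called positive when
#' score >= cutoff.
#'
#' @slot cutoffs swept cutoff values (unique scores and their midpoints).
#' @slot sensitivity,specificity,accuracy metric at each cutoff.
#' @slot selectedCutoff cutoff maximizing the selection criterion.
#' @slot selectionCriterion "accuracy" or "youden".
#' @slot nPositive,nNegative class sizes.
#' @exportClass RocSummary
setClass("RocSummary", representation(
  cutoffs = "numeric",
  sensitivity = "numeric",
  specificity = "numeric",
  accuracy = "numeric",
  selectedCutoff = "numeric",
  selectionCriterion = "character",
  nPositive = "integer",
  nNegative = "integer"
))

setValidity("RocSummary", function(object) {
  m <- c(object@sensitivity, object@specificity, object@accuracy)
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("metrics must lie in [0, 1]")
  TRUE
})
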