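#' @rdname EmbryoSynchrony-accessors
setMethod("embryoId", "LineageTree", function(object) object@embryoId)
#' @rdname EmbryoSynchrony-accessors
setMethod("embryoId", "CountCurve", function(object) object@embryoId)
#' @rdname EmbryoSynchrony-accessors
setMethod("embryoId", "SynchronyProfile", function(object) object@embryoId)

#' @rdname EmbryoSynchrony-accessors
setMethod("nodes", "LineageTree", function(object) object@nodes)

#' @rdname EmbryoSynchrony-accessors
setMethod("intensities", "VoxelGrid", function(object) object@intensities)
#' @rdname EmbryoSynchrony-accessors
setMethod("spacing", "VoxelGrid", function(object) object@spacing)
#' @rdname EmbryoSynchrony-accessors
setMethod("frameTime", "VoxelGrid", function(object) object@time)

#' @rdname EmbryoSynchrony-accessors
setMethod("cleanedCounts", "CountCurve", function(object) object@cleanedCounts)
#' @rdname EmbryoSynchrony-accessors
setMethod("rawCounts", "CountCurve", function(object) object@rawCounts)
#' @rdname EmbryoSynchrony-accessors
setMethod("curveTimes", "CountCurve", function(object) object@times)

#' @rdname EmbryoSynchrony-accessors
setMethod("intraDurations", "StageDurations", function(object) object@intra)
#' @rdname EmbryoSynchrony-accessors
setMethod("interDurations", "StageDurations", function(object) object@inter)

#' @rdname EmbryoSynchrony-accessors
setMethod("thirdCV", "SynchronyProfile", function(object) object@thirdCV)
#' @rdname EmbryoSynchrony-accessors
setMethod("fourthCV", "SynchronyProfile", function(object) object@fourthCV)
#' @rdname EmbryoSynchrony-accessors
setMethod("secondDiffNorm", "SynchronyProfile", function(object) object@secondDiffNorm)
#' @rdname EmbryoSynchrony-accessors
setMethod("synchronyClass", "SynchronyProfile", function(object) object@synchronyClass)

#' @rdname EmbryoSynchrony-accessors
setMethod("selectedCutoff", "RocSummary", function(object) object@selectedCutoff)
#' @rdname EmbryoSynchrony-accessors
setMethod("rocMetrics", "RocSummary", function(object) {
  data.frame(cutoff = object@cutoffs, sensitivity = object@sensitivity,
             specificity = object@specificity, accuracy = object@accuracy)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nEmbryos, "embryo(s)\n")
  cat("  round mean durations [h]:",
      paste(format(object@roundMeanDuration), collapse = ", "), "\n")
  cat("  round CVs:", paste(format(object@roundCV), collapse = ", "), "\n")
  cat("  embryo radius", object@embryoRadius, "um, nucleus radius",
      object@nucleusRadius, "um, step SD", object@motionStepSD, "um\n")
  cat("  frame interval", format(object@frameInterval * 60), "min; voxel",
      paste(object@voxelSpacing, collapse = " x "), "um; volume",
      paste(object@volumeDim, collapse = " x "), "vox; seed", object@seed, "\n")
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VoxelGrid %d x %d x %d voxels, spacing %s um, t = %.3f h (frame %d)\n",
              d[1], d[2], d[3], paste(object@spacing, collapse = "/"),
              object@time, object@frameIndex))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "LineageTree", function(object) {
  nd <- object@nodes
  cat(sprintf("LineageTree '%s': %d node(s), %d division(s)\n",
              object@embryoId, nrow(nd), sum(!is.na(nd$division_time))))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CountCurve", function(object) {
  cat(sprintf("CountCurve '%s': %d frame(s), t in [%.2f, %.2f] h, max count %d\n",
              object@embryoId, length(object@times), min(object@times),
              max(object@times), max(object@cleanedCounts)))
})

setMethod("show", "StageDurations", function(object) {
  cat("StageDurations [h]\n  intra:",
      paste(names(object@intra), format(round(object@intra, 3)), sep = "=",
            collapse = " "), "\n  inter:",
      paste(names(object@inter), format(round(object@inter, 3)), sep = "=",
            collapse = " "), "\n")
  if (length(object@incomplete))
    cat("  incomplete:", paste(object@incomplete, collapse = ", "), "\n")
})

setMethod("show", "SynchronyProfile", function(object) {
  cat(sprintf(
    "SynchronyProfile '%s': second diff %.4f, third CV %.4f, fourth CV %.4f -> %s (cutoff %.2f)\n",
    object@embryoId, object@secondDiffNorm, object@thirdCV, object@fourthCV,
    object@synchronyClass, object@cutoff))
})

setMethod("show", "RocSummary", function(object) {
  i <- which.min(abs(object@cutoffs - object@selectedCutoff))
  cat(sprintf("RocSummary: %d cutoffs, %d abort / %d born\n",
              length(object@cutoffs), object@nPositive, object@nNegative))
  cat(sprintf("  selected cutoff %.4f (%s): sens %.3f, spec %.3f, acc %.3f\n",
              object@selectedCutoff, object@selectionCriterion,
              object@sensitivity[i], object@specificity[i], object@accuracy[i]))
})
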