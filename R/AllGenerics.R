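#' @name EmbryoSynchrony-accessors
#' @title Accessors for EmbryoSynchrony classes
#' @description Slot accessors; user code should use these rather than
#'   \code{@}.
#' @param object an object of the documented class.
#' @return the slot value.
NULL

#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("embryoId", function(object) standardGeneric("embryoId"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("cleanedCounts", function(object) standardGeneric("cleanedCounts"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("rawCounts", function(object) standardGeneric("rawCounts"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("intraDurations", function(object) standardGeneric("intraDurations"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("interDurations", function(object) standardGeneric("interDurations"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("thirdCV", function(object) standardGeneric("thirdCV"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("fourthCV", function(object) standardGeneric("fourthCV"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("secondDiffNorm", function(object) standardGeneric("secondDiffNorm"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("synchronyClass", function(object) standardGeneric("synchronyClass"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("selectedCutoff", function(object) standardGeneric("selectedCutoff"))
#' @rdname EmbryoSynchrony-accessors
#' @export
setGeneric("rocMetrics", function(object) standardGeneric("rocMetrics"))

#' Cell-count curve of an embryo
#'
#' Counts per frame aligned so that the first persistent 1-to-2 transition
#' (first mitosis) is t = 0. For observation tables the raw counts are
#' cleaned to a monotone curve (running maximum, then a 3-point median with
#' end passthrough); lineage trees yield the exact event-based step curve.
#'
#' @param x a nucleus-observation \code{data.frame} (columns \code{frame},
#'   \code{time_h}) or a \linkS4class{LineageTree}.
#' @param ... further arguments passed to methods.
#' @return a \linkS4class{CountCurve}.
#' @examples
#' obs <- data.frame(embryo_id = "e1", frame = 1:5,
#'                   time_h = (0:4), x = 0, y = 0, z = 0)
#' obs <- obs[rep(1:5, times = c(1, 1, 2, 2, 4)), ]
#' countCurve(obs)
#' @export
setGeneric("countCurve", function(x, ...) standardGeneric("countCurve"))
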