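#' @rdname BrainAtlas-class
#' @param x A \code{BrainAtlas}.
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))

#' @rdname BrainAtlas-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname BrainAtlas-class
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname RoiTimeSeriesPanel-class
#' @param x A \code{RoiTimeSeriesPanel}.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname RoiTimeSeriesPanel-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname RoiTimeSeriesPanel-class
#' @export
setGeneric("panelData", function(x) standardGeneric("panelData"))

#' @rdname RoiTimeSeriesPanel-class
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname RoiTimeSeriesPanel-class
#' @export
setGeneric("missingRegions", function(x) standardGeneric("missingRegions"))

#' @rdname MotionTrace-class
#' @param x A \code{MotionTrace}.
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))

setMethod("atlasLabels", "BrainAtlas", function(x) x@labels)
setMethod("nRegions", "BrainAtlas", function(x) nrow(x@labels))
setMethod("regionNames", "BrainAtlas", function(x) x@labels$name)

setMethod("subjectId", "RoiTimeSeriesPanel", function(x) x@subjectId)
setMethod("groupLabel", "RoiTimeSeriesPanel", function(x) x@group)
setMethod("panelData", "RoiTimeSeriesPanel", function(x) x@data)
setMethod("trSeconds", "RoiTimeSeriesPanel", function(x) x@trSeconds)
setMethod("missingRegions", "RoiTimeSeriesPanel",
          function(x) x@missingRegions)

setMethod("motionParams", "MotionTrace", function(x) x@params)
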