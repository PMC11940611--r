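#' @name accessors
#' @title Accessors for scCurate classes
#' @param x an object.
#' @param value replacement value.
#' @description Slot accessors: `cellIds`, `geneIds`, `cellType`,
#'   `tissueLabel`, `donorId`, `typeTissueMap` for [AnnotatedCounts-class];
#'   `classProb`, `maxProb`, `reclassifiedLabel`, `assignedProb` for
#'   [QualityScores-class]; `decisionScores`, `predictedType`, `predictedTissue`
#'   for [PredictionResult-class]; `modelClasses` for [CellTypeModel-class].
NULL

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))
#' @rdname accessors
#' @export
setGeneric("cellType<-", function(x, value) standardGeneric("cellType<-"))
#' @rdname accessors
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))
#' @rdname accessors
#' @export
setGeneric("tissueLabel<-", function(x, value) standardGeneric("tissueLabel<-"))
#' @rdname accessors
#' @export
setGeneric("donorId", function(x) standardGeneric("donorId"))
#' @rdname accessors
#' @export
setGeneric("typeTissueMap", function(x) standardGeneric("typeTissueMap"))
#' @rdname accessors
#' @export
setGeneric("classProb", function(x) standardGeneric("classProb"))
#' @rdname accessors
#' @export
setGeneric("maxProb", function(x) standardGeneric("maxProb"))
#' @rdname accessors
#' @export
setGeneric("reclassifiedLabel", function(x) standardGeneric("reclassifiedLabel"))
#' @rdname accessors
#' @export
setGeneric("assignedProb", function(x) standardGeneric("assignedProb"))
#' @rdname accessors
#' @export
setGeneric("decisionScores", function(x) standardGeneric("decisionScores"))
#' @rdname accessors
#' @export
setGeneric("predictedType", function(x) standardGeneric("predictedType"))
#' @rdname accessors
#' @export
setGeneric("predictedTissue", function(x) standardGeneric("predictedTissue"))
#' @rdname accessors
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))
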