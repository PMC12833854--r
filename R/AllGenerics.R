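#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' @rdname TumorStudy-class
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname TumorStudy-class
#' @export
setGeneric("studyDays", function(x) standardGeneric("studyDays"))

#' @rdname TumorStudy-class
#' @export
setGeneric("studyUnit", function(x) standardGeneric("studyUnit"))

#' @rdname TumorStudy-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname TumorStudy-class
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname TumorStudy-class
#' @export
setGeneric("burdenMatrix", function(x) standardGeneric("burdenMatrix"))

#' @rdname TumorStudy-class
#' @export
setGeneric("excludedMatrix", function(x) standardGeneric("excludedMatrix"))

#' @rdname TumorStudy-class
#' @export
setGeneric("terminalWeights", function(x) standardGeneric("terminalWeights"))

#' @rdname TumorStudy-class
#' @export
setGeneric("euthanasiaDays", function(x) standardGeneric("euthanasiaDays"))

#' @rdname TGRMatrix-class
#' @export
setGeneric("tgrDays", function(x) standardGeneric("tgrDays"))

#' @rdname TGRMatrix-class
#' @export
setGeneric("tgrRates", function(x) standardGeneric("tgrRates"))

#' @rdname TGRMatrix-class
#' @export
setGeneric("tgrOwner", function(x) standardGeneric("tgrOwner"))

#' @rdname TGRMatrix-class
#' @export
setGeneric("isAggregated", function(x) standardGeneric("isAggregated"))
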