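#' @rdname MethSeqSet
#' @param x,object A package object.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname MethSeqSet
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname MethSeqSet
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))

#' @rdname MethSeqSet
#' @export
setGeneric("positiveCount", function(x) standardGeneric("positiveCount"))

#' @rdname MethSeqSet
#' @export
setGeneric("negativeCount", function(x) standardGeneric("negativeCount"))

#' @rdname FeatureSelector
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' @rdname FeatureSelector
#' @export
setGeneric("nSelected", function(x) standardGeneric("nSelected"))

#' @rdname ConvNet
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
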