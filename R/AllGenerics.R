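#' @rdname OrthogroupSet-class
#' @param x an object
#' @export
setGeneric("familyIDs", function(x) standardGeneric("familyIDs"))

#' @rdname OrthogroupSet-class
#' @export
setGeneric("genomeIDs", function(x) standardGeneric("genomeIDs"))

#' @rdname OrthogroupSet-class
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))

#' @rdname OrthogroupMatrix-class
#' @param x an object
#' @export
setGeneric("geneCount", function(x) standardGeneric("geneCount"))

#' @rdname OrthogroupMatrix-class
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname FamilyClassification-class
#' @param x an object
#' @export
setGeneric("familyCategories", function(x) standardGeneric("familyCategories"))

#' @rdname FamilyClassification-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname FamilyClassification-class
#' @export
setGeneric("categoryPercentages",
           function(x) standardGeneric("categoryPercentages"))

#' @rdname FamilyClassification-class
#' @export
setGeneric("singletonGenes", function(x) standardGeneric("singletonGenes"))

#' @rdname RarefactionResult-class
#' @param x an object
#' @export
setGeneric("panCurve", function(x) standardGeneric("panCurve"))

#' @rdname RarefactionResult-class
#' @export
setGeneric("coreCurve", function(x) standardGeneric("coreCurve"))

#' @rdname RarefactionResult-class
#' @export
setGeneric("rarefactionSummary",
           function(x, probs = c(0.025, 0.5, 0.975))
               standardGeneric("rarefactionSummary"))

#' @rdname GeneModelSet-class
#' @param x an object
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
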