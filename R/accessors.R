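#' @describeIn OrthogroupSet-class family identifiers
#' @export
setMethod("familyIDs", "OrthogroupSet", function(x) names(x@members))

#' @describeIn OrthogroupSet-class genome identifiers
#' @export
setMethod("genomeIDs", "OrthogroupSet", function(x) x@genomes)

#' @describeIn OrthogroupSet-class per-family member gene lists
#' @export
setMethod("familyMembers", "OrthogroupSet", function(x) x@members)

#' @describeIn OrthogroupMatrix-class family identifiers (row order)
#' @export
setMethod("familyIDs", "OrthogroupMatrix",
          function(x) rownames(x@geneCount))

#' @describeIn OrthogroupMatrix-class genome identifiers (column order)
#' @export
setMethod("genomeIDs", "OrthogroupMatrix",
          function(x) colnames(x@geneCount))

#' @describeIn OrthogroupMatrix-class the family x genome gene-count matrix
#' @export
setMethod("geneCount", "OrthogroupMatrix", function(x) x@geneCount)

#' @describeIn OrthogroupMatrix-class number of genomes occupied per family
#' @export
setMethod("occupancy", "OrthogroupMatrix",
          function(x) {
              occ <- as.integer(rowSums(x@geneCount > 0))
              names(occ) <- rownames(x@geneCount)
              occ
          })

#' @describeIn FamilyClassification-class named factor of category labels
#' @export
setMethod("familyCategories", "FamilyClassification", function(x) x@category)

#' @describeIn FamilyClassification-class occupancy per family
#' @export
setMethod("occupancy", "FamilyClassification", function(x) x@occupancy)

#' @describeIn FamilyClassification-class family counts per category
#' @export
setMethod("categoryCounts", "FamilyClassification",
          function(x) table(x@category))

#' @describeIn FamilyClassification-class category percentages of all families
#' @export
setMethod("categoryPercentages", "FamilyClassification",
          function(x) 100 * table(x@category) / length(x@category))

#' @describeIn FamilyClassification-class singleton genes outside any family
#' @export
setMethod("singletonGenes", "FamilyClassification", function(x) x@singletons)

#' @describeIn RarefactionResult-class permutations x k matrix of pan sizes
#' @export
setMethod("panCurve", "RarefactionResult", function(x) x@pan)

#' @describeIn RarefactionResult-class permutations x k matrix of core sizes
#' @export
setMethod("coreCurve", "RarefactionResult", function(x) x@core)

#' @describeIn RarefactionResult-class per-k mean and quantiles of both curves
#' @param probs quantile probabilities
#' @export
setMethod("rarefactionSummary", "RarefactionResult",
          function(x, probs = c(0.025, 0.5, 0.975)) {
              k <- seq_len(ncol(x@pan))
              qn <- function(m) t(apply(m, 2, stats::quantile, probs = probs))
              pq <- qn(x@pan); cq <- qn(x@core)
              colnames(pq) <- paste0("pan_q", probs)
              colnames(cq) <- paste0("core_q", probs)
              data.frame(k = k,
                         pan_mean = colMeans(x@pan),
                         core_mean = colMeans(x@core),
                         pq, cq, check.names = FALSE, row.names = NULL)
          })

#' @describeIn GeneModelSet-class gene spans as a named GRanges
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @describeIn GeneModelSet-class exon intervals per transcript
#' @export
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

#' @describeIn GeneModelSet-class CDS intervals per transcript
#' @export
setMethod("cdsRanges", "GeneModelSet", function(x) x@cds)

setMethod("show", "OrthogroupSet", function(object) {
    cat(sprintf("OrthogroupSet: %d families x %d genomes\n",
                length(object@members), length(object@genomes)))
    cat("genomes:", paste(utils::head(object@genomes, 8), collapse = ", "),
        if (length(object@genomes) > 8) "..." else "", "\n")
})

setMethod("show", "OrthogroupMatrix", function(object) {
    occ <- rowSums(object@geneCount > 0)
    cat(sprintf("OrthogroupMatrix: %d families x %d genomes\n",
                nrow(object@geneCount), ncol(object@geneCount)))
    cat(sprintf("occupancy range: %d..%d\n", min(occ), max(occ)))
})

setMethod("show", "CategoryScheme", function(object) {
    n <- object@nGenomes
    band <- function(a, b) if (a > b) "(empty)" else
        if (a == b) sprintf("%d", a) else sprintf("%d-%d", a, b)
    cat(sprintf("CategoryScheme for %d genomes\n", n))
    cat(sprintf("  core: %d | softcore: %s | dispensable: %s | private: 1\n",
                n, band(object@softcoreMin, object@coreMin - 1L),
                band(2L, object@softcoreMin - 1L)))
})

setMethod("show", "FamilyClassification", function(object) {
    cat(sprintf("FamilyClassification: %d families", length(object@category)))
    if (length(object@singletons))
        cat(sprintf(" + %d singleton genes", length(object@singletons)))
    cat("\n")
    cc <- table(object@category)
    pc <- 100 * cc / sum(cc)
    for (lv in names(cc))
        cat(sprintf("  %-12s %6d (%5.2f%%)\n", lv, cc[[lv]], pc[[lv]]))
})

setMethod("show", "RarefactionResult", function(object) {
    cat(sprintf("RarefactionResult: %d orderings (%s) over %d genomes\n",
                nrow(object@pan), object@method, ncol(object@pan)))
    cat(sprintf("  pan(N) = %d, core(N) = %d\n",
                object@pan[1L, ncol(object@pan)],
                object@core[1L, ncol(object@core)]))
})

setMethod("show", "GeneModelSet", function(object) {
    cat(sprintf("GeneModelSet: %d genes, %d transcripts on %d sequence(s)\n",
                length(object@genes), nrow(object@txGene),
                length(unique(as.character(GenomicRanges::seqnames(object@genes))))))
})
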