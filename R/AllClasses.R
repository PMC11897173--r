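#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand findOverlaps
#'   start end width
#' @importFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData rowData<-
NULL

CATEGORY_LEVELS <- c("core", "softcore", "dispensable", "private")
IMPACT_LEVELS <- c("high", "moderate", "low", "modifier")
REGION_LEVELS <- c("cds", "exon_noncoding", "intron", "promoter_upstream",
                   "downstream", "intergenic")
TISSUE_LEVELS <- c("mycelium", "fruiting_body")
SVTYPE_LEVELS <- c("INS", "DEL", "DUP", "INV", "TRA")

#' OrthogroupSet: a collection of orthogroup families with their member genes
#'
#' Holds one entry per family; each entry is a named list mapping every genome
#' in the panel to a (possibly empty) character vector of gene identifiers.
#' The genome set is identical across families and a gene identifier may occur
#' in at most one family.
#'
#' @slot members named list (family -> named list genome -> character).
#' @slot genomes character vector of genome identifiers (column order).
#' @export
setClass("OrthogroupSet",
         slots = c(members = "list", genomes = "character"))

setValidity("OrthogroupSet", function(object) {
    msgs <- character()
    if (length(object@genomes) < 1L)
        msgs <- c(msgs, "at least one genome required")
    if (anyDuplicated(names(object@members)))
        msgs <- c(msgs, "duplicate family identifiers")
    for (fam in names(object@members)) {
        m <- object@members[[fam]]
        if (!identical(sort(names(m)), sort(object@genomes))) {
            msgs <- c(msgs, sprintf("family %s: genome set differs from panel",
                                    fam))
            break
        }
    }
    genes <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(genes)) {
        dup <- unique(genes[duplicated(genes)])[1L]
        fams <- names(object@members)[vapply(object@members, function(m)
            dup %in% unlist(m, use.names = FALSE), logical(1))]
        msgs <- c(msgs, sprintf(
            "gene '%s' assigned to multiple families: %s",
            dup, paste(fams, collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' OrthogroupMatrix: family x genome gene-count matrix
#'
#' The substrate of all pan-genome statistics: an integer matrix with one row
#' per family and one column per genome, entries counting member genes.
#' Families absent from every genome are disallowed (occupancy >= 1).
#'
#' @slot geneCount integer matrix with family rownames and genome colnames.
#' @export
setClass("OrthogroupMatrix", slots = c(geneCount = "matrix"))

setValidity("OrthogroupMatrix", function(object) {
    m <- object@geneCount
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("geneCount must have family rownames and genome colnames")
    if (!is.numeric(m) || any(m < 0) || any(m != round(m)))
        return("geneCount entries must be non-negative integers")
    occ <- rowSums(m > 0)
    if (any(occ == 0))
        return(sprintf("families with zero occupancy are disallowed: %s",
                       paste(utils::head(rownames(m)[occ == 0], 3),
                             collapse = ", ")))
    if (anyDuplicated(rownames(m))) return("duplicate family identifiers")
    if (anyDuplicated(colnames(m))) return("duplicate genome identifiers")
    TRUE
})

#' CategoryScheme: occupancy bands for pan-genome classification
#'
#' Families are classified by the number of genomes they occupy: core
#' (all N genomes), softcore (softcoreMin .. N-1), dispensable
#' (2 .. softcoreMin-1) and private (exactly 1). The default scheme for a
#' panel of N genomes places softcoreMin at N-2, reproducing the bands
#' core = N, softcore = N-2..N-1, dispensable = 2..N-3, private = 1; for
#' small panels the softcore/dispensable bands clamp to empty.
#'
#' @slot nGenomes integer, panel size (>= 2).
#' @slot coreMin integer, minimum occupancy for core (always nGenomes).
#' @slot softcoreMin integer, minimum occupancy for softcore.
#' @export
setClass("CategoryScheme",
         slots = c(nGenomes = "integer", coreMin = "integer",
                   softcoreMin = "integer"))

setValidity("CategoryScheme", function(object) {
    n <- object@nGenomes
    if (length(n) != 1L || n < 2L) return("nGenomes must be a single integer >= 2")
    if (object@coreMin != n) return("coreMin must equal nGenomes")
    if (object@softcoreMin < 2L || object@softcoreMin > object@coreMin)
        return("softcoreMin must satisfy 2 <= softcoreMin <= coreMin")
    TRUE
})

#' FamilyClassification: per-family pan-genome category labels
#'
#' @slot category named factor (family -> core/softcore/dispensable/private).
#' @slot occupancy named integer vector parallel to category.
#' @slot scheme the CategoryScheme that produced the labels.
#' @slot singletons character vector of singleton gene ids (genes outside any
#'   family, tallied as private units but reported separately).
#' @export
setClass("FamilyClassification",
         slots = c(category = "factor", occupancy = "integer",
                   scheme = "CategoryScheme", singletons = "character"))

setValidity("FamilyClassification", function(object) {
    if (!identical(levels(object@category), CATEGORY_LEVELS))
        return("category levels must be core/softcore/dispensable/private")
    if (length(object@category) != length(object@occupancy))
        return("category and occupancy lengths differ")
    if (any(is.na(object@category))) return("NA category")
    TRUE
})

#' RarefactionResult: pan/core curves over genome-order permutations
#'
#' For each sampled (or exhaustively enumerated) ordering of the genomes, the
#' cumulative pan size (families present in at least one of the first k
#' genomes) and core size (families present in all of the first k) are
#' recorded for k = 1..N.
#'
#' @slot pan integer matrix, permutations x k.
#' @slot core integer matrix, permutations x k.
#' @slot method "sample" or "exhaustive".
#' @slot seed integer seed used when sampling (NA for exhaustive).
#' @export
setClass("RarefactionResult",
         slots = c(pan = "matrix", core = "matrix", method = "character",
                   seed = "integer"))

setValidity("RarefactionResult", function(object) {
    if (!identical(dim(object@pan), dim(object@core)))
        return("pan and core dimensions differ")
    # monotonicity within every permutation
    if (ncol(object@pan) > 1L) {
        dpan <- object@pan[, -1L, drop = FALSE] -
            object@pan[, -ncol(object@pan), drop = FALSE]
        dcore <- object@core[, -1L, drop = FALSE] -
            object@core[, -ncol(object@core), drop = FALSE]
        if (any(dpan < 0)) return("pan curve must be non-decreasing in k")
        if (any(dcore > 0)) return("core curve must be non-increasing in k")
    }
    TRUE
})

#' GeneModelSet: gene models with transcript exon/CDS structure
#'
#' Gene spans are held as a GRanges named by gene id; exon and CDS intervals
#' are held per transcript. Coordinates are 1-based closed (Bioconductor
#' convention); GFF3 input needs no shifting.
#'
#' @slot genes GRanges of gene spans, names are gene ids, strand recorded.
#' @slot exons GRangesList of exons per transcript (sorted, non-overlapping).
#' @slot cds GRangesList of CDS intervals per transcript.
#' @slot txGene data.frame with columns tx_id, gene_id.
#' @export
setClass("GeneModelSet",
         slots = c(genes = "GRanges", exons = "GRangesList",
                   cds = "GRangesList", txGene = "data.frame"))

setValidity("GeneModelSet", function(object) {
    if (anyDuplicated(names(object@genes)))
        return("duplicate gene identifiers")
    if (!all(object@txGene$gene_id %in% names(object@genes)))
        return("transcript mapped to unknown gene")
    if (!all(as.character(GenomicRanges::strand(object@genes)) %in% c("+", "-")))
        return("gene strand must be '+' or '-'")
    TRUE
})

#' ExpressionStudy: counts plus sample sheet as a SummarizedExperiment
#'
#' The "counts" assay holds non-negative integer counts; colData carries the
#' sample sheet (genome_id, tissue, replicate). Normalization adds a "cpm"
#' assay (and "tpm" when gene lengths are supplied).
#'
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
    cd <- SummarizedExperiment::colData(object)
    need <- c("genome_id", "tissue", "replicate")
    if (!all(need %in% colnames(cd)))
        return("colData must have genome_id, tissue, replicate")
    if (!all(as.character(cd$tissue) %in% TISSUE_LEVELS))
        return("tissue must be 'mycelium' or 'fruiting_body'")
    if (any(cd$replicate < 1) || any(cd$replicate != round(cd$replicate)))
        return("replicate must be a positive integer")
    key <- paste(cd$genome_id, cd$tissue, cd$replicate)
    if (anyDuplicated(key))
        return("(genome_id, tissue, replicate) triples must be unique")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("missing 'counts' assay")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
        return("counts must be non-negative integers")
    TRUE
})
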