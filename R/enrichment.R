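#' GO term over-representation test
#'
#' One-sided hypergeometric (Fisher) enrichment of a study gene set against a
#' population: for each term with at least one study hit, the upper-tail
#' probability of drawing as many or more annotated genes when sampling the
#' study set from the population without replacement. Associations are taken
#' as flat gene -> term sets; no ontology-graph propagation to ancestor terms
#' is performed (supply pre-propagated associations if that behaviour is
#' wanted). Rows with raw p below \code{alpha} are flagged enriched; a
#' Benjamini-Hochberg column is reported for reference but does not drive
#' the flag.
#'
#' @param study character vector of study gene ids (subset of population).
#' @param population character vector of population gene ids.
#' @param associations named list gene_id -> GO term ids (see
#'   [readGoAssociations()]); genes absent from the list count as
#'   unannotated.
#' @param alpha reporting cutoff on the raw p-value (default 0.05).
#' @return data.frame sorted by p: term_id, study_hits, study_size,
#'   population_hits, population_size, fold_enrichment, p_value, fdr,
#'   enriched.
#' @export
goEnrich <- function(study, population, associations, alpha = 0.05) {
    study <- unique(study)
    population <- unique(population)
    outside <- setdiff(study, population)
    if (length(outside))
        stop("study gene(s) not in population: ",
             paste(utils::head(outside, 5), collapse = ", "))
    assoc <- associations[names(associations) %in% population]
    n <- length(study)
    N <- length(population)

    termGenes <- invertAssociations(assoc)
    k <- vapply(termGenes, function(g) sum(g %in% study), integer(1))
    keep <- k > 0L
    if (!any(keep))
        stop("associations cover no study gene")
    termGenes <- termGenes[keep]; k <- k[keep]
    K <- lengths(termGenes)

    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(term_id = names(termGenes),
                      study_hits = k, study_size = n,
                      population_hits = as.integer(K), population_size = N,
                      fold_enrichment = (k / n) / (K / N),
                      p_value = p, fdr = bhAdjust(p),
                      enriched = p < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
    out[order(out$p_value, out$term_id), , drop = FALSE]
}

# term -> member genes (deduplicated)
invertAssociations <- function(assoc) {
    genes <- rep(names(assoc), lengths(assoc))
    terms <- unlist(assoc, use.names = FALSE)
    if (is.null(terms)) return(list())
    lapply(split(genes, terms), unique)
}
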