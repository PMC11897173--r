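#' Promoter and downstream windows for gene models
#'
#' Promoter windows are strand-aware intervals of \code{width} bases
#' immediately upstream of the transcription start (gene 5' end); downstream
#' windows sit immediately after the gene 3' end. Windows never overlap the
#' gene span and are trimmed at position 1.
#'
#' @param gms a [GeneModelSet-class].
#' @param width window width in bp (defaults: promoter 1000, downstream 500).
#' @return a named GRanges parallel to \code{geneRanges(gms)}.
#' @export
promoterRanges <- function(gms, width = 1000L) {
    flankTrimmed(geneRanges(gms), width, start = TRUE)
}

#' @rdname promoterRanges
#' @export
downstreamRanges <- function(gms, width = 500L) {
    flankTrimmed(geneRanges(gms), width, start = FALSE)
}

flankTrimmed <- function(gr, width, start) {
    fl <- GenomicRanges::flank(gr, width = width, start = start)
    GenomicRanges::start(fl) <- pmax(GenomicRanges::start(fl), 1L)
    GenomicRanges::end(fl) <- pmax(GenomicRanges::end(fl), 0L)
    fl
}

#' Build an overlap index over gene spans and regulatory windows
#'
#' Combines gene spans, promoter windows and downstream windows into one
#' GRanges (tagged by \code{gene_id} and \code{window}) so that a single
#' \code{findOverlaps} query retrieves every gene a variant could affect.
#'
#' @param gms a [GeneModelSet-class].
#' @param promoterLen promoter window width (bp).
#' @param downstreamLen downstream window width (bp).
#' @return a GRanges with metadata columns \code{gene_id}, \code{window}.
#' @export
buildGeneIndex <- function(gms, promoterLen = 1000L, downstreamLen = 500L) {
    if (anyDuplicated(names(geneRanges(gms))))
        stop("duplicate gene_id")
    g <- geneRanges(gms)
    tag <- function(gr, w) {
        out <- granges0(gr)
        out$gene_id <- names(g)
        out$window <- w
        out
    }
    c(tag(g, "span"),
      tag(promoterRanges(gms, promoterLen), "promoter"),
      tag(downstreamRanges(gms, downstreamLen), "downstream"))
}

#' Query a gene index
#'
#' @param index GRanges from [buildGeneIndex()].
#' @param query a GRanges of query intervals.
#' @return data.frame (query_idx, gene_id, window), one row per hit,
#'   duplicate (query, gene, window) pairs removed.
#' @export
queryGeneIndex <- function(index, query) {
    hits <- GenomicRanges::findOverlaps(query, index, ignore.strand = TRUE)
    df <- unique(data.frame(
        query_idx = S4Vectors::queryHits(hits),
        gene_id = index$gene_id[S4Vectors::subjectHits(hits)],
        window = index$window[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE))
    df[order(df$query_idx, df$gene_id, df$window), , drop = FALSE]
}

impactRank <- function(x) match(x, IMPACT_LEVELS)
regionRank <- function(x) match(x, REGION_LEVELS)

#' Precompute plain-numeric gene features for fast impact classification
#'
#' Extracts gene spans, windows and per-transcript exon/CDS coordinates into
#' ordinary vectors so that repeated [classifyImpact()] calls avoid S4
#' range-object overhead. Computed automatically when not supplied.
#'
#' @param gms a [GeneModelSet-class].
#' @param promoterLen,downstreamLen window widths in bp.
#' @return an opaque list keyed by gene id (class "geneFeatures").
#' @export
geneFeatures <- function(gms, promoterLen = 1000L, downstreamLen = 500L) {
    g <- geneRanges(gms)
    prom <- promoterRanges(gms, promoterLen)
    down <- downstreamRanges(gms, downstreamLen)
    tx_ids <- gms@txGene$tx_id
    ex_flat <- unlist(gms@exons[tx_ids], use.names = TRUE)
    cds_flat <- unlist(gms@cds[tx_ids], use.names = TRUE)
    byTx <- function(v, nm) split(v, factor(nm, levels = tx_ids))
    ex_s <- byTx(GenomicRanges::start(ex_flat), names(ex_flat))
    ex_e <- byTx(GenomicRanges::end(ex_flat), names(ex_flat))
    cds_s <- byTx(GenomicRanges::start(cds_flat), names(cds_flat))
    cds_e <- byTx(GenomicRanges::end(cds_flat), names(cds_flat))
    tx_by_gene <- split(tx_ids, gms@txGene$gene_id)
    out <- lapply(names(g), function(gid) {
        list(chrom = as.character(GenomicRanges::seqnames(g[gid])),
             start = GenomicRanges::start(g)[match(gid, names(g))],
             end = GenomicRanges::end(g)[match(gid, names(g))],
             prom = c(GenomicRanges::start(prom)[match(gid, names(g))],
                      GenomicRanges::end(prom)[match(gid, names(g))]),
             down = c(GenomicRanges::start(down)[match(gid, names(g))],
                      GenomicRanges::end(down)[match(gid, names(g))]),
             tx = lapply(tx_by_gene[[gid]], function(t)
                 list(xs = ex_s[[t]], xe = ex_e[[t]],
                      cs = cds_s[[t]], ce = cds_e[[t]])))
    })
    names(out) <- names(g)
    class(out) <- "geneFeatures"
    out
}

# Overlapping bases between [s,e] and a set of intervals (1-based closed).
overlapBases <- function(s, e, starts, ends) {
    if (length(starts) == 0L) return(0L)
    sum(pmax(0L, pmin(e, ends) - pmax(s, starts) + 1L))
}

inAny <- function(pos, starts, ends) {
    length(starts) > 0L && any(pos >= starts & pos <= ends)
}

#' Classify the impact of one structural variant on one gene
#'
#' Implements the rule table mapping (SV type, gene region, frame effect) to
#' an impact class, in the high / moderate / low / modifier convention of
#' variant-effect predictors:
#' \itemize{
#'   \item DEL overlapping CDS: \emph{high} when the removed CDS length is
#'     not a multiple of 3 or the start/stop-bearing CDS end is removed,
#'     otherwise \emph{moderate} (in-frame).
#'   \item DUP overlapping CDS: \emph{high} when the duplicated CDS length is
#'     not a multiple of 3, otherwise \emph{moderate}.
#'   \item INV: \emph{high} when a breakpoint falls inside CDS; an inversion
#'     spanning the CDS with both breakpoints outside it (including one
#'     containing the whole gene) is \emph{moderate}.
#'   \item INS anchored in CDS: \emph{high} if its length is not a multiple
#'     of 3, else \emph{moderate}.
#'   \item Any variant touching exon but not CDS (UTR-equivalent):
#'     \emph{low}.
#'   \item Entirely intronic: \emph{modifier}; promoter-upstream or
#'     downstream window: \emph{modifier}.
#'   \item TRA breakend: \emph{high} in CDS, \emph{moderate} elsewhere in the
#'     gene, \emph{modifier} in the windows.
#' }
#' With multiple transcripts the most severe call wins. The variant must
#' intersect the gene span, promoter or downstream window (pre-filter with
#' [queryGeneIndex()]).
#'
#' @param sv a length-1 GRanges with \code{sv_id}, \code{svtype},
#'   \code{svLength} (as from [readSvVcf()]).
#' @param geneId gene identifier present in \code{gms}.
#' @param gms a [GeneModelSet-class].
#' @param promoterLen,downstreamLen window widths in bp.
#' @return one-row data.frame: sv_id, gene_id, region, impact, rationale.
#' @export
classifyImpact <- function(sv, geneId, gms, promoterLen = 1000L,
                           downstreamLen = 500L, features = NULL) {
    stopifnot(length(sv) == 1L)
    if (is.null(features))
        features <- geneFeatures(gms, promoterLen, downstreamLen)
    ft <- features[[geneId]]
    if (is.null(ft)) stop("unknown gene id: ", geneId)
    classifyImpactCore(as.character(sv$svtype), GenomicRanges::start(sv),
                       GenomicRanges::end(sv), sv$svLength,
                       as.character(GenomicRanges::seqnames(sv)),
                       sv$sv_id, ft, geneId)
}

# plain-argument core shared by classifyImpact and annotateSvImpacts
classifyImpactCore <- function(svtype, s, e, svlen, chrom, sv_id, ft,
                               geneId) {
    sameChrom <- chrom == ft$chrom
    hitGene <- sameChrom && e >= ft$start && s <= ft$end
    if (!hitGene) {
        hitProm <- sameChrom && e >= ft$prom[1L] && s <= ft$prom[2L]
        hitDown <- sameChrom && e >= ft$down[1L] && s <= ft$down[2L]
        if (!hitProm && !hitDown)
            stop(sprintf("SV %s does not intersect gene %s or its windows",
                         sv_id, geneId))
        region <- if (hitProm) "promoter_upstream" else "downstream"
        rationale <- sprintf("%s in %s window", svtype,
                             if (hitProm) "promoter" else "downstream")
        return(impactRow(sv_id, geneId, region, "modifier", rationale))
    }
    calls <- lapply(ft$tx, function(t)
        classifyImpactTx(svtype, s, e, svlen, t$xs, t$xe, t$cs, t$ce))
    best <- calls[[1L]]
    if (length(calls) > 1L) {
        rank <- vapply(calls, function(x)
            impactRank(x$impact) * 10L + regionRank(x$region), integer(1))
        best <- calls[[which.min(rank)]]
    }
    impactRow(sv_id, geneId, best$region, best$impact, best$rationale)
}

impactRow <- function(sv_id, gene_id, region, impact, rationale) {
    data.frame(sv_id = sv_id, gene_id = gene_id, region = region,
               impact = impact, rationale = rationale,
               stringsAsFactors = FALSE)
}

# one transcript's call; coordinates 1-based closed, sv span [s,e];
# xs/xe exon starts/ends, cs/ce CDS starts/ends (plain integer vectors)
classifyImpactTx <- function(svtype, s, e, svlen, xs, xe, cs, ce) {

    if (svtype %in% c("INS", "TRA")) {
        a <- s  # width-1 anchor
        if (inAny(a, cs, ce)) {
            if (svtype == "TRA")
                return(list(region = "cds", impact = "high",
                            rationale = "TRA breakend in CDS"))
            if (svlen %% 3L != 0L)
                return(list(region = "cds", impact = "high",
                            rationale = "INS frameshift in CDS"))
            return(list(region = "cds", impact = "moderate",
                        rationale = "INS in-frame in CDS"))
        }
        region <- if (inAny(a, xs, xe)) "exon_noncoding" else "intron"
        if (svtype == "TRA")
            return(list(region = region, impact = "moderate",
                        rationale = "TRA breakend in gene body"))
        impact <- if (region == "exon_noncoding") "low" else "modifier"
        return(list(region = region, impact = impact,
                    rationale = paste("INS in", region)))
    }

    ovCds <- overlapBases(s, e, cs, ce)
    if (ovCds > 0L) {
        if (svtype == "INV") {
            bkIn <- inAny(s, cs, ce) || inAny(e, cs, ce)
            if (bkIn)
                return(list(region = "cds", impact = "high",
                            rationale = "INV breakpoint in CDS"))
            return(list(region = "cds", impact = "moderate",
                        rationale = "INV spanning CDS, breakpoints outside"))
        }
        if (svtype == "DEL") {
            terminalLoss <- length(cs) > 0L &&
                ((s <= min(cs) && e >= min(cs)) || (s <= max(ce) && e >= max(ce)))
            if (terminalLoss)
                return(list(region = "cds", impact = "high",
                            rationale = "DEL removes start/stop-bearing CDS end"))
            if (ovCds %% 3L != 0L)
                return(list(region = "cds", impact = "high",
                            rationale = "DEL frameshift in CDS"))
            return(list(region = "cds", impact = "moderate",
                        rationale = "DEL in-frame in CDS"))
        }
        # DUP
        if (ovCds %% 3L != 0L)
            return(list(region = "cds", impact = "high",
                        rationale = "DUP frameshift in CDS"))
        return(list(region = "cds", impact = "moderate",
                    rationale = "DUP in-frame in CDS"))
    }
    if (overlapBases(s, e, xs, xe) > 0L)
        return(list(region = "exon_noncoding", impact = "low",
                    rationale = paste(svtype, "in exon outside CDS")))
    list(region = "intron", impact = "modifier",
         rationale = paste(svtype, "intronic"))
}

#' Annotate all structural variants against all gene models
#'
#' Overlap-joins variants with gene spans and regulatory windows (via
#' [buildGeneIndex()]) and classifies every (variant, gene) pair with
#' [classifyImpact()]. Output row order is deterministic (sv_id, gene_id).
#'
#' @param svs GRanges of SVs (see [readSvVcf()]).
#' @param gms a [GeneModelSet-class].
#' @param promoterLen,downstreamLen window widths in bp.
#' @return data.frame: sv_id, gene_id, region, impact, rationale.
#' @export
annotateSvImpacts <- function(svs, gms, promoterLen = 1000L,
                              downstreamLen = 500L) {
    index <- buildGeneIndex(gms, promoterLen, downstreamLen)
    hits <- queryGeneIndex(index, svs)
    pairs <- unique(hits[, c("query_idx", "gene_id")])
    if (nrow(pairs) == 0L)
        return(impactRow(character(0), character(0), character(0),
                         character(0), character(0)))
    feats <- geneFeatures(gms, promoterLen, downstreamLen)
    sv_s <- GenomicRanges::start(svs); sv_e <- GenomicRanges::end(svs)
    sv_type <- as.character(svs$svtype); sv_len <- svs$svLength
    sv_chrom <- as.character(GenomicRanges::seqnames(svs))
    sv_ids <- svs$sv_id
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        q <- pairs$query_idx[i]
        classifyImpactCore(sv_type[q], sv_s[q], sv_e[q], sv_len[q],
                           sv_chrom[q], sv_ids[q],
                           feats[[pairs$gene_id[i]]], pairs$gene_id[i])
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$sv_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Tally SVs and genes by impact class
#'
#' Each SV is counted once at its most severe impact across the genes it
#' touches; each gene once at its most severe impact across the SVs touching
#' it.
#'
#' @param annotations data.frame from [annotateSvImpacts()].
#' @return list with \code{sv_counts} and \code{gene_counts}, named integer
#'   vectors over high/moderate/low/modifier.
#' @export
summarizeImpacts <- function(annotations) {
    tallyMax <- function(key) {
        if (nrow(annotations) == 0L)
            return(stats::setNames(integer(length(IMPACT_LEVELS)),
                                   IMPACT_LEVELS))
        best <- tapply(impactRank(annotations$impact), annotations[[key]], min)
        tab <- table(factor(IMPACT_LEVELS[best], levels = IMPACT_LEVELS))
        stats::setNames(as.integer(tab), names(tab))
    }
    list(sv_counts = tallyMax("sv_id"), gene_counts = tallyMax("gene_id"))
}
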