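#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features (via \pkg{rtracklayer}) and assembles a
#' [GeneModelSet-class]. Transcripts without explicit exon features get a
#' single exon spanning the transcript. CDS intervals are sorted and checked
#' for containment within their gene span.
#'
#' @param path path to a GFF3 file.
#' @return a [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
    stopifnot(file.exists(path))
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    genes <- gr[type == "gene"]
    if (length(genes) == 0L) stop("GFF3 contains no gene features")
    if (any(!as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
        stop("gene with unknown strand ('.'/'*') is not supported")
    names(genes) <- gff3Id(genes)
    if (anyDuplicated(names(genes)))
        stop("duplicate gene IDs in GFF3")

    tx <- gr[type %in% c("mRNA", "transcript")]
    tx_id <- gff3Id(tx)
    tx_parent <- vapply(tx$Parent, `[`, character(1), 1L)
    txGene <- data.frame(tx_id = tx_id, gene_id = tx_parent,
                         stringsAsFactors = FALSE)
    if (!all(txGene$gene_id %in% names(genes)))
        stop("transcript with Parent not matching any gene ID")

    pickChildren <- function(what) {
        feat <- gr[type == what]
        par <- if (length(feat)) vapply(feat$Parent, `[`, character(1), 1L)
               else character(0)
        if (!all(par %in% tx_id))
            stop(what, " feature with Parent not matching any transcript")
        GenomicRanges::sort(
            GenomicRanges::split(granges0(feat), factor(par, levels = tx_id)))
    }
    exons <- pickChildren("exon")
    cds <- pickChildren("CDS")
    # exonless transcripts default to a single exon spanning the transcript
    empty <- lengths(exons) == 0L
    if (any(empty)) {
        ex_list <- as.list(exons)
        spans <- granges0(tx)
        for (i in which(empty)) ex_list[[i]] <- spans[i]
        exons <- GenomicRanges::GRangesList(ex_list)
    }

    # CDS must sit within its gene span
    cds_flat <- unlist(cds, use.names = TRUE)
    if (length(cds_flat)) {
        gi <- txGene$gene_id[match(names(cds_flat), txGene$tx_id)]
        bad <- GenomicRanges::start(cds_flat) <
            GenomicRanges::start(genes)[match(gi, names(genes))] |
            GenomicRanges::end(cds_flat) >
            GenomicRanges::end(genes)[match(gi, names(genes))]
        if (any(bad))
            stop(sprintf("CDS of transcript %s extends outside gene %s",
                         names(cds_flat)[bad][1L], gi[bad][1L]))
    }

    new("GeneModelSet",
        genes = granges0(genes, keep_names = TRUE),
        exons = exons,
        cds = cds,
        txGene = txGene)
}

gff3Id <- function(gr) {
    id <- gr$ID
    if (is.null(id) || any(is.na(id))) stop("GFF3 feature without ID attribute")
    as.character(id)
}

# strip metadata columns, optionally keeping names
granges0 <- function(gr, keep_names = FALSE) {
    nm <- names(gr)
    out <- GenomicRanges::granges(gr)
    names(out) <- if (keep_names) nm else NULL
    out
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features in the layout [readGeneModels()]
#' consumes; coordinates round-trip exactly.
#'
#' @param x a [GeneModelSet-class].
#' @param path output path.
#' @export
writeGeneModels <- function(x, path) {
    stopifnot(is(x, "GeneModelSet"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    writeLines(provenanceComment("writeGeneModels"), con)
    fmt <- function(gr, strands, type, attr) {
        sprintf("%s\tpangene\t%s\t%d\t%d\t.\t%s\t.\t%s",
                as.character(GenomicRanges::seqnames(gr)), type,
                GenomicRanges::start(gr), GenomicRanges::end(gr),
                strands, attr)
    }
    gstrand <- as.character(GenomicRanges::strand(x@genes))
    names(gstrand) <- names(x@genes)
    writeLines(fmt(x@genes, gstrand, "gene",
                   paste0("ID=", names(x@genes))), con)

    tx_strand <- gstrand[x@txGene$gene_id]
    spans <- unlist(range(x@exons[x@txGene$tx_id]))
    writeLines(fmt(spans, tx_strand, "mRNA",
                   sprintf("ID=%s;Parent=%s", x@txGene$tx_id,
                           x@txGene$gene_id)), con)

    emitChildren <- function(grl, tag, type) {
        flat <- unlist(grl[x@txGene$tx_id], use.names = TRUE)
        if (length(flat) == 0L) return(invisible(NULL))
        tx_of <- names(flat)
        idx <- as.integer(stats::ave(seq_along(tx_of), tx_of,
                                     FUN = seq_along))
        strands <- tx_strand[match(tx_of,  x@txGene$tx_id)]
        writeLines(fmt(flat, strands, type,
                       sprintf("ID=%s.%s%d;Parent=%s", tx_of, tag, idx,
                               tx_of)), con)
    }
    emitChildren(x@exons, "e", "exon")
    emitChildren(x@cds, "c", "CDS")
    invisible(path)
}
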