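# Shared fixture builders; everything is generated in code.

# OrthogroupSet from a compact spec: list(fam = list(A = c("g1"), B = ...))
makeOrthogroupSet <- function(spec, genomes) {
    members <- lapply(spec, function(m) {
        full <- stats::setNames(rep(list(character(0)), length(genomes)),
                                genomes)
        full[names(m)] <- lapply(m, as.character)
        full
    })
    new("OrthogroupSet", members = members, genomes = genomes)
}

# OrthogroupMatrix with planted occupancies: for each family, the first
# occ[i] genomes (rotated by i for variety) are occupied with count 1
makeOccupancyMatrix <- function(occ, nGenomes, genomes = NULL) {
    if (is.null(genomes)) genomes <- sprintf("G%02d", seq_len(nGenomes))
    m <- matrix(0L, length(occ), nGenomes,
                dimnames = list(sprintf("F%05d", seq_along(occ)), genomes))
    for (i in seq_along(occ)) {
        cols <- ((i + seq_len(occ[i]) - 2L) %% nGenomes) + 1L
        m[i, cols] <- 1L
    }
    new("OrthogroupMatrix", geneCount = m)
}

# a single 2-exon/UTR gene model (same geometry the generator uses):
# exon1 [s, s+239] (UTR s..s+59), intron, exon2 [s+360, s+659]
# (CDS to s+599, UTR after)
toyTwoExonGene <- function(start = 2000L, strand = "+", id = "gA") {
    pangene:::buildGeneModelSet(id, as.integer(start),
                                as.integer(start + 659L), strand,
                                list(pangene:::geneGeometry("two_exon")))
}

makeSv <- function(svtype, start, end, len = end - start + 1L,
                   id = "sv1", chrom = "chr1") {
    GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start, end), sv_id = id,
        svtype = factor(svtype,
                        levels = c("INS", "DEL", "DUP", "INV", "TRA")),
        svLength = as.integer(len))
}

# ExpressionStudy from a bare count matrix; samples named g<i>_t_r
makeStudy <- function(counts, genomes = NULL, tissue = "mycelium") {
    ns <- ncol(counts)
    if (is.null(genomes)) genomes <- rep("S1", ns)
    sheet <- data.frame(sample_id = colnames(counts), genome_id = genomes,
                        tissue = tissue,
                        replicate = stats::ave(seq_len(ns),
                                               paste(genomes, tissue),
                                               FUN = seq_along))
    ExpressionStudy(counts, sheet)
}
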