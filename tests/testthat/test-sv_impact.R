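# Toy gene geometry used throughout (start 2000, "+" unless noted):
#   exon1 [2000, 2239] with 5'UTR [2000, 2059], CDS1 [2060, 2239]
#   intron [2240, 2359]
#   exon2 [2360, 2659] with CDS2 [2360, 2599], 3'UTR [2600, 2659]

test_that("gene index retrieves genes by span, promoter and downstream", {
    gms <- toyTwoExonGene()
    idx <- buildGeneIndex(gms)
    # between windows: nothing
    hits <- queryGeneIndex(idx, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(10, 20)))
    expect_identical(nrow(hits), 0L)
    # promoter-only query
    hits <- queryGeneIndex(idx, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(1500, 1510)))
    expect_identical(hits$gene_id, "gA")
    expect_identical(hits$window, "promoter")
})

test_that("gene index agrees with a linear-scan oracle on random queries", {
    set.seed(7)
    n <- 200
    starts <- cumsum(sample(2400:4000, n))
    geo <- lapply(rep(c("two_exon", "single"), length.out = n),
                  pangene:::geneGeometry)
    lens <- vapply(geo, `[[`, integer(1), "len")
    strands <- sample(c("+", "-"), n, replace = TRUE)
    gms <- pangene:::buildGeneModelSet(sprintf("g%03d", 1:n),
                                       starts, starts + lens - 1L,
                                       strands, geo)
    idx <- buildGeneIndex(gms, 1000L, 500L)

    g <- geneRanges(gms)
    prom <- promoterRanges(gms, 1000L)
    down <- downstreamRanges(gms, 500L)
    qs <- sample(max(GenomicRanges::end(g)), 300)
    qe <- qs + sample(0:2000, 300, replace = TRUE)
    query <- GenomicRanges::GRanges("chr1", IRanges::IRanges(qs, qe))

    hits <- queryGeneIndex(idx, query)
    for (i in sample(300, 40)) {
        ov <- function(r) qe[i] >= GenomicRanges::start(r) &
            qs[i] <= GenomicRanges::end(r)
        expected <- sort(unique(names(g)[ov(g) | ov(prom) | ov(down)]))
        got <- sort(unique(hits$gene_id[hits$query_idx == i]))
        expect_identical(got, expected)
    }
})

test_that("impact rule table assigns the documented classes", {
    gms <- toyTwoExonGene()
    cls <- function(sv) classifyImpact(sv, "gA", gms)

    # 440 bp promoter insertion: modifier, promoter_upstream
    r <- cls(makeSv("INS", 1900, 1900, 440))
    expect_identical(r$impact, "modifier")
    expect_identical(r$region, "promoter_upstream")

    # 3 bp deletion inside CDS: in-frame, moderate
    expect_identical(cls(makeSv("DEL", 2100, 2102))$impact, "moderate")
    # 4 bp deletion inside CDS: frameshift, high
    expect_identical(cls(makeSv("DEL", 2100, 2103))$impact, "high")
    # deletion removing the CDS 5' terminus: high even if in-frame
    expect_identical(cls(makeSv("DEL", 2058, 2060))$impact, "high")
    # UTR-only deletion: low
    r <- cls(makeSv("DEL", 2010, 2019))
    expect_identical(r$impact, "low")
    expect_identical(r$region, "exon_noncoding")
    # intronic deletion: modifier
    r <- cls(makeSv("DEL", 2250, 2269))
    expect_identical(r$impact, "modifier")
    expect_identical(r$region, "intron")
    # in-frame insertion in CDS: moderate; frameshift insertion: high
    expect_identical(cls(makeSv("INS", 2100, 2100, 6))$impact, "moderate")
    expect_identical(cls(makeSv("INS", 2100, 2100, 7))$impact, "high")
    # duplication of 6 CDS bases: moderate; of 7: high
    expect_identical(cls(makeSv("DUP", 2100, 2105))$impact, "moderate")
    expect_identical(cls(makeSv("DUP", 2100, 2106))$impact, "high")
    # inversion with a breakpoint in CDS: high
    expect_identical(cls(makeSv("INV", 2100, 2500))$impact, "high")
    # inversion containing the whole gene: moderate
    expect_identical(cls(makeSv("INV", 1990, 2700))$impact, "moderate")
    # TRA breakend: high in CDS, moderate in intron, modifier in windows
    expect_identical(cls(makeSv("TRA", 2100, 2100, 1))$impact, "high")
    expect_identical(cls(makeSv("TRA", 2300, 2300, 1))$impact, "moderate")
    expect_identical(cls(makeSv("TRA", 1500, 1500, 1))$impact, "modifier")
    # downstream window: modifier
    r <- cls(makeSv("DEL", 2700, 2719))
    expect_identical(r$impact, "modifier")
    expect_identical(r$region, "downstream")

    # no intersection is a caller error
    expect_error(cls(makeSv("DEL", 10, 20)), "does not intersect")
})

test_that("every (svtype, region) combination yields exactly one impact", {
    gms <- toyTwoExonGene()
    anchors <- list(cds = c(2100L, 2102L), exon_noncoding = c(2010L, 2012L),
                    intron = c(2300L, 2302L),
                    promoter_upstream = c(1500L, 1502L),
                    downstream = c(2700L, 2702L))
    for (svtype in c("INS", "DEL", "DUP", "INV", "TRA")) {
        for (region in names(anchors)) {
            a <- anchors[[region]]
            sv <- if (svtype %in% c("INS", "TRA"))
                makeSv(svtype, a[1], a[1], 7) else makeSv(svtype, a[1], a[2])
            r <- classifyImpact(sv, "gA", gms)
            expect_identical(nrow(r), 1L)
            expect_true(r$impact %in% c("high", "moderate", "low",
                                        "modifier"))
            expect_identical(r$region, region)
        }
    }
})

test_that("impact classes are invariant under strand mirroring", {
    # mirror the gene to '-' and reflect SV coordinates around the gene
    # midpoint; the class depends only on feature membership
    plus <- toyTwoExonGene(2000L, "+")
    minus <- pangene:::buildGeneModelSet(
        "gA", 2000L, 2659L, "-",
        list(list(len = 660L,
                  exons = rbind(c(0L, 299L), c(420L, 659L)),
                  cds = rbind(c(60L, 299L), c(420L, 599L)))))
    reflect <- function(s, e) {
        lo <- 2000L + 2659L - e; hi <- 2000L + 2659L - s
        c(lo, hi)
    }
    cases <- list(c(2100L, 2102L), c(2100L, 2103L), c(2010L, 2019L),
                  c(2320L, 2339L), c(2620L, 2629L))
    for (svtype in c("DEL", "DUP", "INV")) {
        for (cs in cases) {
            r1 <- classifyImpact(makeSv(svtype, cs[1], cs[2]), "gA", plus)
            m <- reflect(cs[1], cs[2])
            r2 <- classifyImpact(makeSv(svtype, m[1], m[2]), "gA", minus)
            expect_identical(r2$impact, r1$impact)
            expect_identical(r2$region, r1$region)
        }
    }
})

test_that("impact summaries count SVs and genes at their maximum impact", {
    ann <- data.frame(
        sv_id = c("sv1", "sv1", "sv2"),
        gene_id = c("gA", "gB", "gB"),
        region = "cds",
        impact = c("high", "modifier", "moderate"),
        rationale = "r")
    s <- summarizeImpacts(ann)
    expect_identical(s$sv_counts[["high"]], 1L)      # sv1 at its max
    expect_identical(s$sv_counts[["moderate"]], 1L)  # sv2
    expect_identical(s$gene_counts[["high"]], 1L)    # gA
    expect_identical(s$gene_counts[["moderate"]], 1L) # gB max over sv1, sv2
    expect_identical(sum(s$sv_counts), 2L)
    expect_identical(sum(s$gene_counts), 2L)

    z <- summarizeImpacts(ann[0, ])
    expect_true(all(z$sv_counts == 0L))
})

test_that("annotation is deterministic and recovers planted classes", {
    cfg <- simulationConfig(seed = 13L)
    pg <- simulatePangenome(cfg)
    ann_sim <- simulateAnnotation(cfg, pg)
    for (g in cfg$exprGenomes[1:2]) {
        got <- annotateSvImpacts(ann_sim$svs[[g]], ann_sim$geneModels[[g]])
        got2 <- annotateSvImpacts(ann_sim$svs[[g]], ann_sim$geneModels[[g]])
        expect_identical(got, got2)
        truth <- ann_sim$impacts[ann_sim$impacts$genome_id == g, ]
        m <- merge(got, truth, by = c("sv_id", "gene_id"))
        expect_identical(nrow(m), nrow(truth))
        expect_identical(nrow(got), nrow(truth))
        expect_identical(m$impact.x, m$impact.y)
        expect_identical(m$region.x, m$region.y)
    }
})
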