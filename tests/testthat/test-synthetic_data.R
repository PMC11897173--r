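test_that("simulation is byte-deterministic under a fixed seed", {
    cfg <- simulationConfig(seed = 31L)
    s1 <- simulateStudy(cfg)
    s2 <- simulateStudy(cfg)
    expect_identical(familyMembers(s1$orthogroups),
                     familyMembers(s2$orthogroups))
    expect_identical(SummarizedExperiment::assay(s1$study, "counts"),
                     SummarizedExperiment::assay(s2$study, "counts"))
    expect_identical(s1$impactsTruth, s2$impactsTruth)
    expect_identical(s1$goAssociations, s2$goAssociations)

    # a different seed changes the draw
    s3 <- simulatePangenome(simulationConfig(seed = 32L))
    expect_false(identical(s3$truth$pattern, s1$pangenomeTruth$pattern))
})

test_that("planted family categories are recovered exactly by classification", {
    cfg <- simulationConfig(seed = 33L, scaleFactor = 1,
                            familyCounts = c(core = 10, softcore = 5,
                                             dispensable = 8, private = 3),
                            nSingletons = 0)
    pg <- simulatePangenome(cfg)
    cl <- classifyFamilies(orthogroupMatrix(pg$orthogroups))
    expect_identical(as.vector(categoryCounts(cl)), c(10L, 5L, 8L, 3L))
    expect_identical(
        unname(as.character(
            familyCategories(cl)[pg$truth$family_id])),
        pg$truth$category)

    # all-core config
    cfgC <- simulationConfig(seed = 34L, scaleFactor = 1,
                             familyCounts = c(core = 12, softcore = 0,
                                              dispensable = 0, private = 0),
                             nSingletons = 0)
    clC <- classifyFamilies(orthogroupMatrix(
        simulatePangenome(cfgC)$orthogroups))
    expect_identical(unname(as.vector(categoryCounts(clC))),
                     c(12L, 0L, 0L, 0L))
})

test_that("sv_rate 0 produces empty VCF bodies", {
    cfg <- simulationConfig(seed = 35L, svRate = 0)
    pg <- simulatePangenome(cfg)
    ann <- simulateAnnotation(cfg, pg)
    expect_true(all(vapply(ann$svs, length, integer(1)) == 0L))
    expect_identical(nrow(ann$impacts), 0L)
    tf <- withr::local_tempfile(fileext = ".vcf")
    writeSvVcf(ann$svs$S1, tf)
    body <- grep("^#", readLines(tf), invert = TRUE, value = TRUE)
    expect_identical(length(body), 0L)
})

test_that("the affected genome always carries the 440 bp promoter insertion", {
    cfg <- simulationConfig(seed = 36L)
    pg <- simulatePangenome(cfg)
    ann <- simulateAnnotation(cfg, pg)
    anchor <- ann$impacts[ann$impacts$gene_id == ann$anchorGene, ]
    expect_identical(nrow(anchor), 1L)
    expect_identical(anchor$genome_id, cfg$affectedGenome)
    expect_identical(anchor$kind, "promoter_ins")
    expect_true(anchor$expression_effect)
    sv <- ann$svs[[cfg$affectedGenome]]
    rec <- sv[sv$sv_id == anchor$sv_id]
    expect_identical(as.character(rec$svtype), "INS")
    expect_identical(rec$svLength, 440L)
    # and the classifier sees it as a promoter modifier
    got <- classifyImpact(rec, ann$anchorGene,
                          ann$geneModels[[cfg$affectedGenome]])
    expect_identical(got$region, "promoter_upstream")
    expect_identical(got$impact, "modifier")
})

test_that("near-zero dispersion gives Poisson-like counts", {
    cfg <- simulationConfig(seed = 37L, dispersion = 0, svRate = 0,
                            libJitter = 0)
    pg <- simulatePangenome(cfg)
    cts <- simulateCounts(cfg, pg)
    m <- SummarizedExperiment::assay(cts$study, "counts")
    sel <- cts$truth$genome_id == "S1" & cts$truth$category == "core"
    sub <- m[cts$truth$gene_id[sel],
             SummarizedExperiment::colData(cts$study)$genome_id == "S1"]
    ratio <- apply(sub, 1, var) / rowMeans(sub)
    # variance-to-mean ratio concentrates around 1 across genes
    expect_equal(mean(ratio), 1, tolerance = 0.15)

    # positive dispersion should inflate the variance well beyond Poisson
    cfg2 <- simulationConfig(seed = 37L, dispersion = 0.3, svRate = 0,
                             libJitter = 0)
    cts2 <- simulateCounts(cfg2, simulatePangenome(cfg2))
    m2 <- SummarizedExperiment::assay(cts2$study, "counts")
    sub2 <- m2[cts2$truth$gene_id[sel],
               SummarizedExperiment::colData(cts2$study)$genome_id == "S1"]
    expect_gt(mean(apply(sub2, 1, var) / rowMeans(sub2)), 5)
})

test_that("all generator outputs parse through the readers without warnings", {
    cfg <- simulationConfig(seed = 38L)
    sim <- simulateStudy(cfg)
    td <- withr::local_tempdir()
    f <- function(...) file.path(td, ...)
    expect_no_warning({
        writeOrthogroups(sim$orthogroups, f("og.tsv"))
        og <- readOrthogroups(f("og.tsv"))
        writeGeneModels(sim$geneModels$S1, f("S1.gff3"))
        gm <- readGeneModels(f("S1.gff3"))
        writeSvVcf(sim$svs$S1, f("S1.vcf"))
        sv <- readSvVcf(f("S1.vcf"))
        writeCounts(sim$study, f("counts.tsv"))
        sheet <- data.frame(
            sample_id = colnames(sim$study),
            as.data.frame(SummarizedExperiment::colData(sim$study)),
            row.names = NULL)
        writeSampleSheet(sheet, f("sheet.tsv"))
        study <- readCounts(f("counts.tsv"), readSampleSheet(f("sheet.tsv")))
        writeGoAssociations(sim$goAssociations, f("go.tsv"))
        go <- readGoAssociations(f("go.tsv"))
    })
    expect_identical(familyMembers(og), familyMembers(sim$orthogroups))
    expect_identical(S4Vectors::metadata(sv)$n_skipped, 0L)
    expect_identical(
        SummarizedExperiment::assay(study, "counts"),
        SummarizedExperiment::assay(sim$study, "counts"))
})

test_that("planted fold changes are recovered by the DE caller", {
    cfg <- simulationConfig(seed = 39L)
    sim <- simulateStudy(cfg)
    hom <- singleCopyHomologs(sim$orthogroups, cfg$exprGenomes)
    hstudy <- normalizeStudy(homologCountMatrix(sim$study, hom))
    cd <- SummarizedExperiment::colData(hstudy)
    ga <- rownames(cd)[cd$genome_id == "S1" & cd$tissue == "mycelium"]
    gb <- rownames(cd)[cd$genome_id == "S3" & cd$tissue == "mycelium"]
    de <- callDE(hstudy, ga, gb)

    eff <- sim$impactsTruth[sim$impactsTruth$expression_effect, ]
    gmap <- geneFamilyMap(sim$orthogroups)
    # groups whose S1 member carries an effect: expect lfc near +2
    fam_s1 <- unname(gmap[eff$gene_id[eff$genome_id == "S1"]])
    fam_s1 <- intersect(fam_s1, hom$family_id)
    # exclude groups also perturbed in S3
    fam_s3 <- unname(gmap[eff$gene_id[eff$genome_id == "S3"]])
    fam_s1 <- setdiff(fam_s1, fam_s3)
    est <- de$log2_fold_change[match(fam_s1, de$gene_id)]
    expect_gt(length(est), 5)
    expect_lt(mean(abs(est - cfg$plantedLfc)), 0.3)
})
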