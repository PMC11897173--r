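test_that("CPM normalization scales columns to one million", {
    m <- matrix(c(10L, 30L, 0L, 0L), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    cpm <- cpmMatrix(m)
    expect_equal(cpm[, "s1"], c(g1 = 2.5e5, g2 = 7.5e5))
    expect_identical(attr(cpm, "zero_total"), "s2")
    expect_true(all(is.na(cpm[, "s2"])))

    # single expressed gene takes the whole million
    expect_equal(unname(cpmMatrix(matrix(10L, 1, 1,
        dimnames = list("g", "s")))[1, 1]), 1e6)

    # column-sum property on random matrices
    set.seed(1)
    r <- matrix(rpois(600, 20), 60, 10,
                dimnames = list(sprintf("g%02d", 1:60),
                                sprintf("s%02d", 1:10)))
    expect_equal(unname(colSums(cpmMatrix(r))), rep(1e6, 10))
    # TPM with lengths also sums to a million
    expect_equal(unname(colSums(tpmMatrix(r, sample(200:2000, 60)))),
                 rep(1e6, 10))
})

test_that("Benjamini-Hochberg step-up matches the reference implementation", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_identical(bhAdjust(numeric(0)), numeric(0))
    set.seed(2)
    for (i in 1:200) {
        p <- runif(sample(1:60, 1))
        expect_equal(bhAdjust(p), p.adjust(p, "BH"))
    }
    # step-up monotonicity after sorting
    p <- runif(100)
    expect_true(all(diff(bhAdjust(p)[order(p)]) >= -1e-12))
})

test_that("differential expression calls follow the defined test", {
    set.seed(3)
    # identical groups: lfc 0, never a DEG
    m <- cbind(matrix(rep(c(50L, 200L), 4), 2, 4),
               matrix(rep(c(50L, 200L), 4), 2, 4))
    colnames(m) <- sprintf("s%d", 1:8)
    rownames(m) <- c("g1", "g2")
    study <- makeStudy(m)
    de <- callDE(study, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
    expect_equal(de$log2_fold_change, c(0, 0))
    expect_false(any(de$is_deg))

    # group mean CPM 80 vs 10 with tight replicates: lfc ~ log2(80.5/10.5)
    nGenes <- 50
    base <- matrix(1000L, nGenes, 8)
    base[1, 1:4] <- 80L; base[1, 5:8] <- 10L
    # keep library sizes at exactly 1e6 so CPM equals the raw count
    base[2, ] <- 0L
    base[2, ] <- 1e6L - colSums(base)
    dimnames(base) <- list(sprintf("g%02d", 1:nGenes),
                           sprintf("s%d", 1:8))
    st <- makeStudy(base)
    de <- callDE(st, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
    expect_equal(de$log2_fold_change[1], log2(80.5 / 10.5),
                 tolerance = 1e-6)
    expect_true(de$is_deg[1])

    expect_error(callDE(study, "s1", sprintf("s%d", 5:8)), ">= 2")
})

test_that("Welch p-values agree with stats::t.test on random data", {
    set.seed(4)
    for (i in 1:25) {
        a <- matrix(rnorm(4 * 5, mean = 8), 4, 5)
        b <- matrix(rnorm(4 * 6, mean = 8.5), 4, 6)
        p <- pangene:::welchP(a, b)
        ref <- vapply(1:4, function(j)
            t.test(a[j, ], b[j, ])$p.value, numeric(1))
        expect_equal(p, ref, tolerance = 1e-12)
    }
})

test_that("swapping groups negates fold changes and keeps p-values", {
    set.seed(5)
    m <- matrix(rpois(80 * 8, 60), 80, 8,
                dimnames = list(sprintf("g%02d", 1:80),
                                sprintf("s%d", 1:8)))
    st <- makeStudy(m)
    a <- sprintf("s%d", 1:4); b <- sprintf("s%d", 5:8)
    d1 <- callDE(st, a, b); d2 <- callDE(st, b, a)
    expect_equal(d2$log2_fold_change, -d1$log2_fold_change)
    expect_equal(d2$p_value, d1$p_value)
})

test_that("category expression profiles order medians and test globally", {
    cfg <- simulationConfig(seed = 6L)
    pg <- simulatePangenome(cfg)
    cts <- simulateCounts(cfg, pg)
    cl <- classifyFamilies(orthogroupMatrix(pg$orthogroups))
    prof <- categoryExpressionProfile(cts$study, cl,
                                      geneFamilyMap(pg$orthogroups),
                                      "mycelium")
    med <- stats::setNames(prof$profile$median, prof$profile$category)
    # planted ordering core > softcore > dispensable > private
    expect_true(med["core"] > med["softcore"])
    expect_true(med["softcore"] > med["dispensable"])
    expect_true(med["dispensable"] > med["private"])
    expect_lt(prof$kruskal_p, 1e-3)
    # singletons are not family-mapped
    expect_identical(prof$n_unmapped, sum(pg$singletons$genome_id %in%
                                              cfg$exprGenomes))

    # all-identical expression: KW statistic 0, p 1
    m <- matrix(100L, 4, 4, dimnames = list(sprintf("S1_g%04d", 1:4),
                                            sprintf("s%d", 1:4)))
    flat <- makeStudy(m)
    og <- makeOrthogroupSet(
        list(OG1 = list(S1 = "S1_g0001"), OG2 = list(S1 = "S1_g0002"),
             OG3 = list(S1 = c("S1_g0003"), S2 = "S2_g0001"),
             OG4 = list(S1 = "S1_g0004", S2 = "S2_g0002")),
        genomes = c("S1", "S2"))
    cl2 <- classifyFamilies(orthogroupMatrix(og))
    pr2 <- suppressWarnings(categoryExpressionProfile(
        flat, cl2, geneFamilyMap(og), "mycelium"))
    expect_equal(pr2$kruskal_stat, 0)
    expect_equal(pr2$kruskal_p, 1)
})

test_that("Kruskal-Wallis on separated groups matches the rank formula", {
    # two categories, n = 5 each, fully separated values
    expr <- c(1:5, 101:105)
    grp <- factor(rep(c("a", "b"), each = 5))
    kw <- kruskal.test(expr, grp)
    # independent computation from rank sums: H = 12/(N(N+1)) sum R_i^2/n_i - 3(N+1)
    r <- rank(expr)
    H <- 12 / (10 * 11) * (sum(r[1:5])^2 / 5 + sum(r[6:10])^2 / 5) - 3 * 11
    expect_equal(unname(kw$statistic), H)
    expect_equal(kw$p.value, pchisq(H, df = 1, lower.tail = FALSE))
})

test_that("expression breadth counts genomes over the CPM threshold", {
    cfg <- simulationConfig(seed = 8L)
    pg <- simulatePangenome(cfg)
    cts <- simulateCounts(cfg, pg)
    hom <- singleCopyHomologs(pg$orthogroups, cfg$exprGenomes)
    br <- expressionBreadth(cts$study, hom, "mycelium")
    expect_true(all(br$breadth >= 0 & br$breadth <= 5))
    # core genes are planted with the highest means (about 4000 CPM here);
    # at a threshold between core and softcore CPM only core stays broad
    cl <- classifyFamilies(orthogroupMatrix(pg$orthogroups))
    cats <- familyCategories(cl)[br$family_id]
    br_hi <- expressionBreadth(cts$study, hom, "mycelium",
                               threshold = 3000)
    expect_gt(mean(br_hi$breadth[cats == "core"]),
              mean(br_hi$breadth[cats != "core"]))
    # trivial bounds
    expect_true(all(br$breadth[cats == "core"] == 5L))
})

test_that("SV-DEG association reproduces the closed-form chi-square", {
    # 2x2 table [[30, 70], [10, 190]] as (sv, deg) counts
    svAff <- rep(c(TRUE, FALSE), c(100, 200))
    isDeg <- c(rep(c(TRUE, FALSE), c(30, 70)),
               rep(c(TRUE, FALSE), c(10, 190)))
    ar <- svDegAssociation(svAff, isDeg)
    expect_equal(unname(ar$proportions), c(0.30, 0.05))
    # continuity-corrected chi-square computed from first principles
    tab <- matrix(c(30, 10, 70, 190), 2)
    expc <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi <- sum((abs(tab - expc) - 0.5)^2 / expc)
    expect_equal(ar$statistic, chi)
    expect_equal(ar$p_value, pchisq(chi, 1, lower.tail = FALSE))
    expect_identical(ar$method, "chisq")

    # equal proportions: no effect, p ~ 1
    ar0 <- svDegAssociation(rep(c(TRUE, FALSE), each = 100),
                            rep(c(TRUE, FALSE, TRUE, FALSE),
                                c(20, 80, 20, 80)))
    expect_gt(ar0$p_value, 0.95)
    expect_equal(unname(diff(ar0$proportions)), 0)

    # zero margin falls back to Fisher
    arf <- svDegAssociation(rep(c(TRUE, FALSE), each = 5),
                            rep(FALSE, 10))
    expect_identical(arf$method, "fisher")
    expect_equal(arf$p_value, 1)
})

test_that("sporulation ratio is a guarded percentage", {
    expect_equal(sporulationRatio(50, 100), 50)
    expect_equal(sporulationRatio(3.7, 3.7), 100)
    expect_error(sporulationRatio(0, 100), "positive")
    expect_error(sporulationRatio(10, 0), "positive")
})

test_that("homolog count matrices align genes across genomes", {
    og <- makeOrthogroupSet(
        list(OG1 = list(S1 = "S1_a", S2 = "S2_a"),
             OG2 = list(S1 = "S1_b", S2 = "S2_b"),
             OG3 = list(S1 = c("S1_c1", "S1_c2"), S2 = "S2_c")),
        genomes = c("S1", "S2"))
    hom <- singleCopyHomologs(og)
    expect_identical(hom$family_id, c("OG1", "OG2"))  # OG3 not single-copy

    m <- matrix(seq_len(5 * 4) * 10L, 5, 4,
                dimnames = list(c("S1_a", "S1_b", "S1_c1", "S2_a", "S2_b"),
                                c("x1", "x2", "y1", "y2")))
    m <- rbind(m, S2_c = 1L, S1_c2 = 1L)
    st <- makeStudy(m, genomes = rep(c("S1", "S2"), each = 2))
    h <- homologCountMatrix(st, hom)
    cts <- SummarizedExperiment::assay(h, "counts")
    expect_identical(cts["OG1", "x1"], m["S1_a", "x1"])
    expect_identical(cts["OG1", "y2"], m["S2_a", "y2"])
    expect_identical(cts["OG2", "y1"], m["S2_b", "y1"])
})
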