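#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe a panel
#' emulating the structure of a 15-genome fungal pan-genome study with five
#' expression-profiled cultivar genomes: family-category proportions of
#' 5917/1937/5058/575 (core/softcore/dispensable/private) scaled by
#' \code{scaleFactor}, 368 scaled singleton genes, four biological replicates
#' of two tissues per genome, negative-binomial counts with category-graded
#' means, and SV-linked planted fold changes.
#'
#' @param nGenomes panel size (default 15).
#' @param scaleFactor scales the family-category counts so the default suite
#'   runs in seconds (default 0.05, about 675 families); set 1 for full
#'   scale.
#' @param familyCounts named counts per category before scaling.
#' @param nSingletons singleton genes outside any family before scaling.
#' @param exprGenomes genome ids carrying expression data (the cultivar
#'   panel; default S1, S2, S3, S4, S6).
#' @param affectedGenome the genome carrying the guaranteed promoter
#'   insertion with an expression effect (default "S3").
#' @param baseMean baseline negative-binomial mean count (default 50).
#' @param categoryMultipliers strictly decreasing mean multipliers
#'   core > softcore > dispensable > private (default 8, 4, 2, 1).
#' @param dispersion NB dispersion phi, variance = mu + phi mu^2
#'   (default 0.1).
#' @param nReplicates biological replicates per genome and tissue
#'   (default 4).
#' @param svRate fraction of genes per genome receiving one planted SV
#'   (default 0.1).
#' @param affectedFraction fraction of SV-hit genes whose expression is
#'   shifted by \code{plantedLfc} (default 0.8).
#' @param plantedLfc planted log2 fold change on affected gene copies
#'   (default 2).
#' @param promoterLen,downstreamLen regulatory window widths in bp.
#' @param libJitter library-size jitter, uniform in 1 +/- libJitter
#'   (default 0.2).
#' @param seed integer master seed; fixed seed gives byte-identical outputs.
#' @return a validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(nGenomes = 15L,
                             scaleFactor = 0.05,
                             familyCounts = c(core = 5917L, softcore = 1937L,
                                              dispensable = 5058L,
                                              private = 575L),
                             nSingletons = 368L,
                             exprGenomes = c("S1", "S2", "S3", "S4", "S6"),
                             affectedGenome = "S3",
                             baseMean = 50,
                             categoryMultipliers = c(core = 8, softcore = 4,
                                                     dispensable = 2,
                                                     private = 1),
                             dispersion = 0.1,
                             nReplicates = 4L,
                             svRate = 0.1,
                             affectedFraction = 0.8,
                             plantedLfc = 2,
                             promoterLen = 1000L,
                             downstreamLen = 500L,
                             libJitter = 0.2,
                             seed = 1L) {
    cfg <- list(nGenomes = as.integer(nGenomes),
                familyCounts = pmax(0L, as.integer(round(
                    familyCounts * scaleFactor))),
                nSingletons = as.integer(round(nSingletons * scaleFactor)),
                exprGenomes = exprGenomes,
                affectedGenome = affectedGenome,
                baseMean = baseMean,
                categoryMultipliers = categoryMultipliers,
                dispersion = dispersion,
                nReplicates = as.integer(nReplicates),
                svRate = svRate,
                affectedFraction = affectedFraction,
                plantedLfc = plantedLfc,
                promoterLen = as.integer(promoterLen),
                downstreamLen = as.integer(downstreamLen),
                libJitter = libJitter,
                seed = as.integer(seed))
    names(cfg$familyCounts) <- CATEGORY_LEVELS
    stopifnot(cfg$nGenomes >= 2L,
              length(cfg$exprGenomes) <= cfg$nGenomes,
              cfg$affectedGenome %in% cfg$exprGenomes,
              all(diff(cfg$categoryMultipliers) < 0),
              cfg$nReplicates >= 2L,
              cfg$svRate >= 0, cfg$svRate <= 1,
              cfg$affectedFraction >= 0, cfg$affectedFraction <= 1,
              cfg$seed < 2^31 - 10)
    scheme <- defaultScheme(cfg$nGenomes)
    bands <- categoryBands(scheme)
    for (cat_ in CATEGORY_LEVELS)
        if (cfg$familyCounts[[cat_]] > 0L && length(bands[[cat_]]) == 0L)
            stop(sprintf("category '%s' has an empty occupancy band for N=%d",
                         cat_, cfg$nGenomes))
    class(cfg) <- "SimulationConfig"
    cfg
}

categoryBands <- function(scheme) {
    n <- scheme@nGenomes
    list(core = n,
         softcore = seq2(scheme@softcoreMin, n - 1L),
         dispensable = seq2(2L, scheme@softcoreMin - 1L),
         private = 1L)
}

seq2 <- function(a, b) if (a > b) integer(0) else seq.int(a, b)

simGenomeIDs <- function(cfg) {
    extra <- cfg$nGenomes - length(cfg$exprGenomes)
    c(cfg$exprGenomes,
      if (extra > 0L) sprintf("G%02d", seq_len(extra) +
                                  length(cfg$exprGenomes)))
}

#' Simulate an orthogroup table with planted categories
#'
#' Each family is assigned its category's occupancy band (occupancy drawn
#' uniformly within the band), then a uniformly random genome subset of that
#' size; every present genome contributes exactly one member gene.
#' Classifying the result recovers the planted categories exactly.
#'
#' @param config a [simulationConfig()].
#' @return list: \code{orthogroups} ([OrthogroupSet-class]), \code{truth}
#'   (data.frame family_id, category, occupancy, pattern), \code{singletons}
#'   (data.frame gene_id, genome_id).
#' @export
simulatePangenome <- function(config) {
    genomes <- simGenomeIDs(config)
    scheme <- defaultScheme(config$nGenomes)
    bands <- categoryBands(scheme)
    withr::with_seed(config$seed + 1L, {
        cats <- rep(CATEGORY_LEVELS, config$familyCounts)
        nf <- length(cats)
        fam_ids <- sprintf("OG%05d", seq_len(nf))
        counter <- stats::setNames(integer(length(genomes)), genomes)
        members <- vector("list", nf)
        occ <- integer(nf)
        pattern <- character(nf)
        for (i in seq_len(nf)) {
            band <- bands[[cats[i]]]
            k <- if (length(band) == 1L) band else sample(band, 1L)
            subset <- sort(sample(genomes, k))
            m <- stats::setNames(rep(list(character(0)), length(genomes)),
                                 genomes)
            for (g in subset) {
                counter[g] <- counter[g] + 1L
                m[[g]] <- sprintf("%s_g%04d", g, counter[g])
            }
            members[[i]] <- m
            occ[i] <- k
            pattern[i] <- paste(as.integer(genomes %in% subset),
                                collapse = "")
        }
        names(members) <- fam_ids
        singletons <- data.frame(
            gene_id = character(0), genome_id = character(0),
            stringsAsFactors = FALSE)
        if (config$nSingletons > 0L) {
            sg <- sample(config$exprGenomes, config$nSingletons,
                         replace = TRUE)
            singletons <- data.frame(
                gene_id = sprintf("%s_x%03d", sg, seq_len(config$nSingletons)),
                genome_id = sg, stringsAsFactors = FALSE)
        }
        list(orthogroups = new("OrthogroupSet", members = members,
                               genomes = genomes),
             truth = data.frame(family_id = fam_ids, category = cats,
                                occupancy = occ, pattern = pattern,
                                stringsAsFactors = FALSE),
             singletons = singletons)
    })
}

# fixed gene geometries (offsets relative to the gene 5'-most coordinate)
geneGeometry <- function(structure) {
    if (structure == "two_exon")
        list(len = 660L,
             exons = rbind(c(0L, 239L), c(360L, 659L)),
             cds = rbind(c(60L, 239L), c(360L, 599L)))
    else  # intronless, fully coding
        list(len = 300L,
             exons = rbind(c(0L, 299L)),
             cds = rbind(c(0L, 299L)))
}

#' Simulate gene models and structural variants with planted impacts
#'
#' Lays the member genes of each expression genome out on one contig
#' (alternating intronless and two-exon/UTR structures and strands,
#' non-overlapping, with intergenic gaps wide enough that every variant
#' touches exactly one gene), then plants one SV on a configured fraction of
#' genes, cycling through region/type combinations whose impact class is
#' known by construction. Whenever SVs are enabled (svRate > 0), one gene of
#' the affected genome is guaranteed a 440 bp promoter insertion with a
#' planted expression effect.
#'
#' @param config a [simulationConfig()].
#' @param pg result of [simulatePangenome()].
#' @return list: \code{geneModels} (named list of [GeneModelSet-class] per
#'   genome), \code{svs} (named list of GRanges per genome), \code{impacts}
#'   (data.frame genome_id, sv_id, gene_id, region, impact, kind,
#'   expression_effect).
#' @export
simulateAnnotation <- function(config, pg) {
    genomes <- config$exprGenomes
    og <- pg$orthogroups
    # deterministic per-genome gene lists, family order then singletons
    geneLists <- lapply(genomes, function(g) {
        fam_genes <- unlist(lapply(og@members, function(m) m[[g]]),
                            use.names = FALSE)
        c(fam_genes, pg$singletons$gene_id[pg$singletons$genome_id == g])
    })
    names(geneLists) <- genomes

    # the guaranteed promoter-insertion gene: first family present in every
    # expression genome
    anchorFam <- names(og@members)[vapply(og@members, function(m)
        all(lengths(m[genomes]) >= 1L), logical(1))][1L]
    anchorGene <- if (!is.na(anchorFam))
        og@members[[anchorFam]][[config$affectedGenome]][1L] else NA_character_

    withr::with_seed(config$seed + 2L, {
        out_models <- list(); out_svs <- list(); impacts <- list()
        for (g in genomes) {
            genes <- geneLists[[g]]
            n <- length(genes)
            structure <- rep(c("two_exon", "single"), length.out = n)
            strand <- rep(c("+", "-"), length.out = n)
            gap <- config$promoterLen + config$downstreamLen + 900L
            starts <- integer(n); ends <- integer(n)
            pos <- config$promoterLen + 500L
            geo <- lapply(structure, geneGeometry)
            for (i in seq_len(n)) {
                starts[i] <- pos
                ends[i] <- pos + geo[[i]]$len - 1L
                pos <- ends[i] + gap + 1L
            }
            gms <- buildGeneModelSet(genes, starts, ends, strand, geo)
            out_models[[g]] <- gms

            n_sv <- floor(config$svRate * n)
            hit <- if (n_sv > 0L) sort(sample.int(n, n_sv)) else integer(0)
            if (config$svRate > 0 && g == config$affectedGenome &&
                !is.na(anchorGene)) {
                ai <- match(anchorGene, genes)
                if (!ai %in% hit) hit <- sort(c(hit, ai))
            }
            svrows <- list(); imp <- list()
            for (j in seq_along(hit)) {
                i <- hit[j]
                forced <- g == config$affectedGenome &&
                    genes[i] == anchorGene
                kind_id <- if (forced) 1L else ((j - 1L) %% 8L) + 1L
                sv <- plantSv(kind_id, starts[i], ends[i], strand[i],
                              structure[i], config)
                effect <- forced ||
                    stats::runif(1) < config$affectedFraction
                svrows[[j]] <- data.frame(
                    start = sv$start, end = sv$end, svtype = sv$svtype,
                    len = sv$len, stringsAsFactors = FALSE)
                imp[[j]] <- data.frame(
                    genome_id = g, gene_id = genes[i], region = sv$region,
                    impact = sv$impact, kind = sv$kind,
                    expression_effect = effect, stringsAsFactors = FALSE)
            }
            if (length(svrows)) {
                df <- do.call(rbind, svrows)
                gr <- GRanges("chr1", IRanges(df$start, df$end),
                              sv_id = sprintf("%s_sv%03d", g,
                                              seq_len(nrow(df))),
                              svtype = factor(df$svtype,
                                              levels = SVTYPE_LEVELS),
                              svLength = as.integer(df$len))
                out_svs[[g]] <- gr
                impdf <- do.call(rbind, imp)
                impdf$sv_id <- gr$sv_id
                impacts[[g]] <- impdf
            } else {
                out_svs[[g]] <- GRanges(sv_id = character(0),
                                        svtype = factor(character(0),
                                                        levels = SVTYPE_LEVELS),
                                        svLength = integer(0))
            }
        }
        impacts <- if (length(impacts)) do.call(rbind, impacts) else
            data.frame(genome_id = character(0), gene_id = character(0),
                       region = character(0), impact = character(0),
                       kind = character(0), expression_effect = logical(0),
                       sv_id = character(0), stringsAsFactors = FALSE)
        rownames(impacts) <- NULL
        list(geneModels = out_models, svs = out_svs, impacts = impacts,
             anchorGene = anchorGene)
    })
}

buildGeneModelSet <- function(genes, starts, ends, strand, geo) {
    g_gr <- GRanges("chr1", IRanges(starts, ends), strand = strand)
    names(g_gr) <- genes
    tx <- paste0(genes, ".t1")
    flatten <- function(what) {
        per <- lapply(geo, `[[`, what)
        nrows <- vapply(per, nrow, integer(1))
        offs <- do.call(rbind, per)
        i <- rep(seq_along(genes), nrows)
        gr <- GRanges("chr1", IRanges(starts[i] + offs[, 1L],
                                      starts[i] + offs[, 2L]),
                      strand = strand[i])
        GenomicRanges::split(gr, factor(tx[i], levels = tx))
    }
    new("GeneModelSet", genes = g_gr,
        exons = flatten("exons"),
        cds = flatten("cds"),
        txGene = data.frame(tx_id = tx, gene_id = genes,
                            stringsAsFactors = FALSE))
}

# One planted SV for a gene at [s, e]; the intended (region, impact) follows
# the classifier's rule table by construction. Coordinates chosen so the
# variant never reaches a neighbouring gene or its windows.
plantSv <- function(kind_id, s, e, strand, structure, config) {
    promAnchor <- if (strand == "+") s - 100L else e + 100L
    promSpan <- if (strand == "+") c(s - 220L, s - 201L) else
        c(e + 201L, e + 220L)
    downSpan <- if (strand == "+") c(e + 101L, e + 120L) else
        c(s - 120L, s - 101L)
    if (structure == "two_exon") {
        cdsA <- s + 66L
        switch(kind_id,
            list(kind = "promoter_ins", svtype = "INS", start = promAnchor,
                 end = promAnchor, len = 440L,
                 region = "promoter_upstream", impact = "modifier"),
            list(kind = "cds_inframe_del", svtype = "DEL", start = cdsA,
                 end = cdsA + 2L, len = 3L, region = "cds",
                 impact = "moderate"),
            list(kind = "cds_frameshift_del", svtype = "DEL", start = cdsA,
                 end = cdsA + 3L, len = 4L, region = "cds", impact = "high"),
            list(kind = "intron_del", svtype = "DEL", start = s + 250L,
                 end = s + 269L, len = 20L, region = "intron",
                 impact = "modifier"),
            list(kind = "utr_del", svtype = "DEL", start = s + 10L,
                 end = s + 19L, len = 10L, region = "exon_noncoding",
                 impact = "low"),
            list(kind = "cds_frameshift_ins", svtype = "INS",
                 start = s + 100L, end = s + 100L, len = 7L,
                 region = "cds", impact = "high"),
            list(kind = "cds_inframe_dup", svtype = "DUP", start = s + 90L,
                 end = s + 95L, len = 6L, region = "cds",
                 impact = "moderate"),
            list(kind = "inv_cds_breakpoint", svtype = "INV",
                 start = s + 100L, end = e + 340L, len = e + 340L - s - 99L,
                 region = "cds", impact = "high"))
    } else {
        cdsA <- s + 6L
        switch(kind_id,
            list(kind = "promoter_ins", svtype = "INS", start = promAnchor,
                 end = promAnchor, len = 440L,
                 region = "promoter_upstream", impact = "modifier"),
            list(kind = "cds_inframe_del", svtype = "DEL", start = cdsA,
                 end = cdsA + 2L, len = 3L, region = "cds",
                 impact = "moderate"),
            list(kind = "cds_frameshift_del", svtype = "DEL", start = cdsA,
                 end = cdsA + 3L, len = 4L, region = "cds", impact = "high"),
            list(kind = "downstream_del", svtype = "DEL",
                 start = downSpan[1L], end = downSpan[2L], len = 20L,
                 region = "downstream", impact = "modifier"),
            list(kind = "promoter_del", svtype = "DEL",
                 start = promSpan[1L], end = promSpan[2L], len = 20L,
                 region = "promoter_upstream", impact = "modifier"),
            list(kind = "cds_frameshift_ins", svtype = "INS",
                 start = s + 100L, end = s + 100L, len = 7L,
                 region = "cds", impact = "high"),
            list(kind = "cds_inframe_dup", svtype = "DUP", start = s + 90L,
                 end = s + 95L, len = 6L, region = "cds",
                 impact = "moderate"),
            list(kind = "inv_cds_breakpoint", svtype = "INV",
                 start = s + 100L, end = e + 340L, len = e + 340L - s - 99L,
                 region = "cds", impact = "high"))
    }
}

#' Simulate a count matrix with category-graded means and planted effects
#'
#' Per gene and sample, counts are negative-binomial with mean
#' \code{baseMean * multiplier(category) * 2^plantedLfc} (the fold factor
#' applying only to gene copies flagged with an expression effect in the
#' annotation step), scaled by a per-sample library factor jittered within
#' \code{1 +/- libJitter}. Dispersion 0 degrades to Poisson. Singleton genes
#' use the private-category mean.
#'
#' @param config a [simulationConfig()].
#' @param pg result of [simulatePangenome()].
#' @param ann result of [simulateAnnotation()] (or NULL for no effects).
#' @return list: \code{study} ([ExpressionStudy-class]), \code{truth}
#'   (data.frame gene_id, genome_id, category, base_mean, planted_lfc).
#' @export
simulateCounts <- function(config, pg, ann = NULL) {
    genomes <- config$exprGenomes
    og <- pg$orthogroups
    cat_by_fam <- stats::setNames(pg$truth$category, pg$truth$family_id)
    rows <- list()
    for (g in genomes) {
        fam_genes <- unlist(lapply(og@members, function(m) m[[g]]),
                            use.names = FALSE)
        fam_of <- geneFamilyMap(og)[fam_genes]
        df <- data.frame(gene_id = fam_genes, genome_id = g,
                         category = unname(cat_by_fam[fam_of]),
                         stringsAsFactors = FALSE)
        sing <- pg$singletons$gene_id[pg$singletons$genome_id == g]
        if (length(sing))
            df <- rbind(df, data.frame(gene_id = sing, genome_id = g,
                                       category = "private",
                                       stringsAsFactors = FALSE))
        rows[[g]] <- df
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    truth$base_mean <- config$baseMean *
        config$categoryMultipliers[truth$category]
    truth$planted_lfc <- 0
    if (!is.null(ann) && nrow(ann$impacts) > 0L) {
        eff <- ann$impacts$gene_id[ann$impacts$expression_effect]
        truth$planted_lfc[truth$gene_id %in% eff] <- config$plantedLfc
    }

    sheet <- expand.grid(replicate = seq_len(config$nReplicates),
                         tissue = TISSUE_LEVELS, genome_id = genomes,
                         stringsAsFactors = FALSE)
    sheet <- sheet[, c("genome_id", "tissue", "replicate")]
    sheet$sample_id <- sprintf("%s_%s_%d", sheet$genome_id,
                               ifelse(sheet$tissue == "mycelium", "my", "fb"),
                               sheet$replicate)
    withr::with_seed(config$seed + 3L, {
        lib <- stats::runif(nrow(sheet), 1 - config$libJitter,
                            1 + config$libJitter)
        mu_gene <- truth$base_mean * 2^truth$planted_lfc
        counts <- matrix(0L, nrow(truth), nrow(sheet),
                         dimnames = list(truth$gene_id, sheet$sample_id))
        for (j in seq_len(nrow(sheet))) {
            sel <- truth$genome_id == sheet$genome_id[j]
            mu <- mu_gene[sel] * lib[j]
            counts[sel, j] <- as.integer(if (config$dispersion > 0)
                stats::rnbinom(sum(sel), mu = mu,
                               size = 1 / config$dispersion)
            else stats::rpois(sum(sel), mu))
        }
        study <- ExpressionStudy(
            counts, sheet[, c("sample_id", "genome_id", "tissue",
                              "replicate")])
        list(study = normalizeStudy(study), truth = truth)
    })
}

#' Simulate flat gene-to-GO associations
#'
#' Annotation probability decreases from core to private (0.9 / 0.8 / 0.6 /
#' 0.4), echoing the declining annotated fraction across categories seen in
#' real panels; annotated genes draw 1-4 terms from a 40-term pool.
#'
#' @param config a [simulationConfig()].
#' @param countsTruth the \code{truth} component of [simulateCounts()].
#' @return named list gene_id -> character vector of GO ids.
#' @export
simulateGoAssociations <- function(config, countsTruth) {
    pool <- sprintf("GO:%07d", seq_len(40L))
    pAnnot <- c(core = 0.9, softcore = 0.8, dispensable = 0.6,
                private = 0.4)
    withr::with_seed(config$seed + 4L, {
        annotated <- stats::runif(nrow(countsTruth)) <
            pAnnot[countsTruth$category]
        out <- lapply(which(annotated), function(i)
            sort(sample(pool, sample.int(4L, 1L))))
        names(out) <- countsTruth$gene_id[annotated]
        out
    })
}

#' Simulate a complete study with planted ground truth
#'
#' Runs all generator stages in order (pan-genome table, gene models and
#' SVs, counts, GO associations) under one master seed.
#'
#' @param config a [simulationConfig()].
#' @return list with components \code{config}, \code{orthogroups},
#'   \code{pangenomeTruth}, \code{singletons}, \code{geneModels},
#'   \code{svs}, \code{impactsTruth}, \code{study}, \code{countsTruth},
#'   \code{goAssociations}, \code{anchorGene}.
#' @export
simulateStudy <- function(config = simulationConfig()) {
    pg <- simulatePangenome(config)
    ann <- simulateAnnotation(config, pg)
    cts <- simulateCounts(config, pg, ann)
    go <- simulateGoAssociations(config, cts$truth)
    list(config = config,
         orthogroups = pg$orthogroups,
         pangenomeTruth = pg$truth,
         singletons = pg$singletons,
         geneModels = ann$geneModels,
         svs = ann$svs,
         impactsTruth = ann$impacts,
         study = cts$study,
         countsTruth = cts$truth,
         goAssociations = go,
         anchorGene = ann$anchorGene)
}
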