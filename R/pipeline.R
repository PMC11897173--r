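#' Run the full pan-genome analysis pipeline on simulated inputs
#'
#' Executes the stages in dependency order — simulate, classify, rarefy,
#' shared, sv-annotate, de, profile, associate, enrich, report — with every
#' stage reading its inputs from and writing its outputs to \code{outdir},
#' so the pipeline is restartable. A manifest records input checksums and
#' wall times per stage; on re-runs, stages whose inputs are unchanged and
#' whose outputs exist are skipped (checksum equality guarantees identical
#' results). Any stage error aborts with the stage name.
#'
#' Differential expression compares each cultivar genome against the
#' configured affected genome (homolog-group counts, mycelium tissue); a
#' homolog group is a DEG when any comparison flags it.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if missing).
#' @param seed optional integer overriding \code{config$seed}.
#' @param nPerm rarefaction permutations (default 100).
#' @param force re-run all stages even if up to date.
#' @param quiet suppress progress messages.
#' @return (invisibly) the path to \code{report.json}.
#' @export
runPipeline <- function(config = simulationConfig(), outdir,
                        seed = NULL, nPerm = 100L, force = FALSE,
                        quiet = FALSE) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(...) file.path(outdir, ...)

    jsonlite::write_json(unclass(config), pth("config.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest_path <- pth("manifest.json")
    prev <- if (!force && file.exists(manifest_path))
        jsonlite::read_json(manifest_path) else list()
    manifest <- list(seed = config$seed,
                     config_md5 = unname(tools::md5sum(pth("config.json"))),
                     stages = list())
    logmsg <- function(...) if (!quiet)
        message(format(Sys.time(), "[%Y-%m-%dT%H:%M:%S] "), sprintf(...))

    stage <- function(name, inputs, outputs, fun) {
        sums <- as.list(tools::md5sum(inputs))
        old <- prev$stages[[name]]
        up_to_date <- !is.null(old) &&
            length(old$inputs) == length(sums) &&
            identical(unname(unlist(old$inputs)), unname(unlist(sums))) &&
            all(file.exists(outputs))
        if (up_to_date) {
            logmsg("stage %-12s up to date, skipped", name)
            manifest$stages[[name]] <<- old
            return(invisible(NULL))
        }
        logmsg("stage %-12s running", name)
        t0 <- Sys.time()
        tryCatch(fun(), error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        manifest$stages[[name]] <<- list(
            inputs = sums, outputs = as.list(outputs),
            wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")))
        invisible(NULL)
    }

    genomes <- config$exprGenomes
    f_og <- pth("orthogroups.tsv")
    f_single <- pth("singleton_genes.tsv")
    f_gff <- stats::setNames(pth(sprintf("%s.gff3", genomes)), genomes)
    f_vcf <- stats::setNames(pth(sprintf("%s.sv.vcf", genomes)), genomes)
    f_counts <- pth("counts.tsv"); f_sheet <- pth("samples.tsv")
    f_go <- pth("gene2go.tsv"); f_truth <- pth("ground_truth.json")

    stage("simulate", pth("config.json"),
          c(f_og, f_single, f_gff, f_vcf, f_counts, f_sheet, f_go, f_truth),
          function() {
        sim <- simulateStudy(config)
        writeOrthogroups(sim$orthogroups, f_og)
        utils::write.table(sim$singletons, f_single, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        for (g in genomes) {
            writeGeneModels(sim$geneModels[[g]], f_gff[[g]])
            writeSvVcf(sim$svs[[g]], f_vcf[[g]])
        }
        writeCounts(sim$study, f_counts)
        sheet <- data.frame(
            sample_id = colnames(sim$study),
            as.data.frame(SummarizedExperiment::colData(sim$study)),
            row.names = NULL)
        writeSampleSheet(sheet, f_sheet)
        writeGoAssociations(sim$goAssociations, f_go)
        jsonlite::write_json(
            list(pangenome = sim$pangenomeTruth,
                 impacts = sim$impactsTruth,
                 counts = sim$countsTruth,
                 anchor_gene = sim$anchorGene),
            f_truth, auto_unbox = TRUE, digits = NA)
    })

    f_class <- pth("classification.tsv")
    stage("classify", c(f_og, f_single), f_class, function() {
        og <- readOrthogroups(f_og)
        singles <- utils::read.delim(f_single)$gene_id
        cl <- classifyFamilies(orthogroupMatrix(og),
                               singletons = as.character(singles))
        df <- data.frame(family_id = names(familyCategories(cl)),
                         occupancy = unname(occupancy(cl)),
                         category = as.character(familyCategories(cl)))
        con <- file(f_class, "w"); on.exit(close(con))
        writeLines(provenanceComment("classify"), con)
        writeLines(sprintf("# singleton_genes\t%d",
                           length(singletonGenes(cl))), con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    })

    f_rar <- pth("rarefaction.tsv")
    stage("rarefy", f_og, f_rar, function() {
        og <- readOrthogroups(f_og)
        rr <- rarefy(orthogroupMatrix(og), nPerm = nPerm,
                     seed = config$seed)
        pan <- panCurve(rr); core <- coreCurve(rr)
        df <- data.frame(
            permutation = rep(seq_len(nrow(pan)), ncol(pan)),
            k = rep(seq_len(ncol(pan)), each = nrow(pan)),
            pan = as.vector(pan), core = as.vector(core))
        con <- file(f_rar, "w"); on.exit(close(con))
        writeLines(provenanceComment("rarefy",
                                     sprintf("nPerm=%d seed=%d", nPerm,
                                             config$seed)), con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    })

    f_shared <- pth("shared_patterns.tsv")
    stage("shared", f_og, f_shared, function() {
        og <- readOrthogroups(f_og)
        use <- genomes[seq_len(min(5L, length(genomes)))]
        pc <- sharedPatternCounts(orthogroupMatrix(og), use)
        con <- file(f_shared, "w"); on.exit(close(con))
        writeLines(provenanceComment("shared",
                                     paste(use, collapse = ",")), con)
        utils::write.table(
            data.frame(pattern = names(pc), count = pc),
            con, sep = "\t", quote = FALSE, row.names = FALSE)
    })

    f_imp <- pth("sv_impacts.tsv")
    stage("sv_annotate", c(f_gff, f_vcf), f_imp, function() {
        rows <- lapply(genomes, function(g) {
            gms <- readGeneModels(f_gff[[g]])
            svs <- readSvVcf(f_vcf[[g]])
            if (length(svs) == 0L) return(NULL)
            ann <- annotateSvImpacts(svs, gms, config$promoterLen,
                                     config$downstreamLen)
            if (nrow(ann)) cbind(genome_id = g, ann) else NULL
        })
        out <- do.call(rbind, rows)
        con <- file(f_imp, "w"); on.exit(close(con))
        writeLines(provenanceComment("sv_annotate"), con)
        utils::write.table(out, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    })

    f_de <- pth("de.tsv")
    stage("de", c(f_counts, f_sheet, f_og), f_de, function() {
        og <- readOrthogroups(f_og)
        study <- readCounts(f_counts, readSampleSheet(f_sheet))
        hom <- singleCopyHomologs(og, genomes)
        hstudy <- normalizeStudy(homologCountMatrix(study, hom))
        cd <- SummarizedExperiment::colData(hstudy)
        ref <- config$affectedGenome
        res <- lapply(setdiff(genomes, ref), function(g) {
            ga <- rownames(cd)[cd$genome_id == g & cd$tissue == "mycelium"]
            gb <- rownames(cd)[cd$genome_id == ref &
                                   cd$tissue == "mycelium"]
            cbind(comparison = sprintf("%s_vs_%s", g, ref),
                  callDE(hstudy, ga, gb))
        })
        out <- do.call(rbind, res)
        con <- file(f_de, "w"); on.exit(close(con))
        writeLines(provenanceComment("de"), con)
        utils::write.table(out, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    })

    f_prof <- pth("profile.tsv"); f_breadth <- pth("breadth.tsv")
    stage("profile", c(f_counts, f_sheet, f_og, f_class),
          c(f_prof, f_breadth), function() {
        og <- readOrthogroups(f_og)
        study <- normalizeStudy(readCounts(f_counts,
                                           readSampleSheet(f_sheet)))
        singles <- utils::read.delim(f_single)$gene_id
        cl <- classifyFamilies(orthogroupMatrix(og),
                               singletons = as.character(singles))
        gmap <- geneFamilyMap(og)
        prof <- lapply(TISSUE_LEVELS, function(tt)
            categoryExpressionProfile(study, cl, gmap, tt))
        names(prof) <- TISSUE_LEVELS
        out <- do.call(rbind, lapply(TISSUE_LEVELS, function(tt)
            cbind(tissue = tt, prof[[tt]]$profile,
                  kruskal_p = prof[[tt]]$kruskal_p)))
        con <- file(f_prof, "w"); on.exit(close(con))
        writeLines(provenanceComment("profile"), con)
        utils::write.table(out, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)

        hom <- singleCopyHomologs(og, genomes)
        br <- expressionBreadth(study, hom, "mycelium")
        br$category <- as.character(
            familyCategories(cl)[br$family_id])
        con2 <- file(f_breadth, "w")
        on.exit(close(con2), add = TRUE)
        writeLines(provenanceComment("breadth"), con2)
        utils::write.table(br, con2, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    })

    f_assoc <- pth("association.json")
    stage("associate", c(f_de, f_imp, f_og), f_assoc, function() {
        og <- readOrthogroups(f_og)
        hom <- singleCopyHomologs(og, genomes)
        de <- utils::read.delim(f_de, comment.char = "#")
        imp <- utils::read.delim(f_imp, comment.char = "#")
        deg <- tapply(de$is_deg, de$gene_id, any)
        isDeg <- unname(deg[hom$family_id])
        isDeg[is.na(isDeg)] <- FALSE
        svGenes <- unique(imp$gene_id)
        svAff <- apply(as.matrix(hom[, genomes]), 1L,
                       function(r) any(r %in% svGenes))
        ar <- svDegAssociation(svAff, isDeg)
        jsonlite::write_json(
            list(table = as.vector(ar$table),
                 table_labels = c("sv_deg", "nosv_deg", "sv_nodeg",
                                  "nosv_nodeg"),
                 prop_deg_sv = unname(ar$proportions["sv_affected"]),
                 prop_deg_nosv = unname(ar$proportions["not_affected"]),
                 statistic = ar$statistic, p_value = ar$p_value,
                 method = ar$method, n_groups = nrow(hom)),
            f_assoc, auto_unbox = TRUE, digits = NA)
    })

    f_enr <- pth("enrichment.tsv")
    stage("enrich", c(f_imp, f_go, f_counts), f_enr, function() {
        imp <- utils::read.delim(f_imp, comment.char = "#")
        assoc <- readGoAssociations(f_go)
        cts <- utils::read.delim(f_counts, comment.char = "#")
        population <- cts[[1L]]
        studySet <- unique(imp$gene_id[imp$impact == "high"])
        out <- goEnrich(studySet, population, assoc)
        con <- file(f_enr, "w"); on.exit(close(con))
        writeLines(provenanceComment("enrich", "alpha=0.05"), con)
        utils::write.table(out, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    })

    f_repj <- pth("report.json"); f_repm <- pth("report.md")
    stage("report", c(f_class, f_rar, f_shared, f_imp, f_de, f_assoc,
                      f_enr), c(f_repj, f_repm), function() {
        writePipelineReport(outdir)
    })

    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
    logmsg("pipeline complete: %s", pth("report.json"))
    invisible(pth("report.json"))
}

#' Assemble the pipeline summary report
#'
#' Reads the stage outputs in a pipeline directory and writes
#' \code{report.json} and \code{report.md}. Every number printed in the
#' markdown table is present in the JSON summary.
#'
#' @param outdir a directory produced by [runPipeline()].
#' @return (invisibly) the report list.
#' @export
writePipelineReport <- function(outdir) {
    pth <- function(...) file.path(outdir, ...)
    cls <- utils::read.delim(pth("classification.tsv"), comment.char = "#")
    comp <- table(factor(cls$category, levels = CATEGORY_LEVELS))
    pct <- round(100 * comp / sum(comp), 2)
    rar <- utils::read.delim(pth("rarefaction.tsv"), comment.char = "#")
    kmax <- max(rar$k)
    pan_end <- mean(rar$pan[rar$k == kmax])
    core_end <- mean(rar$core[rar$k == kmax])
    shared <- utils::read.delim(pth("shared_patterns.tsv"),
                                comment.char = "#",
                                colClasses = c("character", "integer"))
    all_pat <- strrep("1", nchar(shared$pattern[1L]))
    shared_all <- sum(shared$count[shared$pattern == all_pat])
    shared_frac <- round(100 * shared_all / sum(shared$count), 1)
    imp <- utils::read.delim(pth("sv_impacts.tsv"), comment.char = "#")
    sums <- summarizeImpacts(imp)
    de <- utils::read.delim(pth("de.tsv"), comment.char = "#")
    n_deg <- length(unique(de$gene_id[de$is_deg]))
    assoc <- jsonlite::read_json(pth("association.json"))
    enr <- utils::read.delim(pth("enrichment.tsv"), comment.char = "#")

    report <- list(
        composition = list(counts = as.list(comp),
                           percentages = as.list(as.vector(pct))),
        rarefaction = list(k = kmax, pan_mean = pan_end,
                           core_mean = core_end),
        shared = list(all_present = shared_all,
                      total = sum(shared$count),
                      percent_all_present = shared_frac),
        sv_impacts = list(sv_counts = as.list(sums$sv_counts),
                          gene_counts = as.list(sums$gene_counts)),
        de = list(n_deg_groups = n_deg,
                  n_comparisons = length(unique(de$comparison))),
        association = assoc,
        enrichment = list(n_terms = nrow(enr),
                          n_enriched = sum(enr$enriched)))
    names(report$composition$percentages) <- names(comp)
    jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                         digits = NA)

    md <- c("# Pipeline report", "",
            "## Pan-genome composition", "",
            "| category | families | % |", "|---|---|---|",
            sprintf("| %s | %d | %.2f |", names(comp), as.vector(comp),
                    as.vector(pct)), "",
            sprintf("Rarefaction endpoints at k = %d: pan %.1f, core %.1f",
                    kmax, pan_end, core_end), "",
            sprintf("Shared across all genomes: %d / %d families (%.1f%%)",
                    shared_all, sum(shared$count), shared_frac), "",
            "## SV impact tallies", "",
            "| impact | SVs | genes |", "|---|---|---|",
            sprintf("| %s | %d | %d |", names(sums$sv_counts),
                    as.vector(sums$sv_counts),
                    as.vector(sums$gene_counts)), "",
            sprintf("DEG homolog groups: %d (over %d comparisons)", n_deg,
                    length(unique(de$comparison))), "",
            sprintf(paste("SV-DEG association: DEG rate %.3f (SV) vs %.3f",
                          "(no SV), %s p = %.3g"),
                    assoc$prop_deg_sv, assoc$prop_deg_nosv, assoc$method,
                    assoc$p_value), "",
            sprintf("Enriched GO terms: %d of %d tested",
                    sum(enr$enriched), nrow(enr)))
    writeLines(md, pth("report.md"))
    invisible(report)
}
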