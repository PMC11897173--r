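#' Counts-per-million normalization
#'
#' Scales each sample to one million. Samples with a zero library total
#' cannot be normalized: their columns are set to NA and flagged.
#'
#' @param counts gene x sample numeric matrix.
#' @return matrix of CPM values; attribute \code{zero_total} names excluded
#'   samples.
#' @export
cpmMatrix <- function(counts) {
    totals <- colSums(counts)
    zero <- totals == 0
    if (any(zero)) totals[zero] <- NA_real_
    out <- sweep(counts, 2L, totals, "/") * 1e6
    attr(out, "zero_total") <- colnames(counts)[zero]
    out
}

#' TPM-like normalization given gene lengths
#'
#' Length-normalizes counts before the per-million scaling so that columns
#' again sum to 1e6.
#'
#' @param counts gene x sample numeric matrix.
#' @param lengths per-gene lengths in bp, aligned with rows.
#' @return matrix of TPM values.
#' @export
tpmMatrix <- function(counts, lengths) {
    stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
    rate <- counts / lengths
    cpmMatrix(rate)
}

#' Add normalized assays to an expression study
#'
#' @param study an [ExpressionStudy-class].
#' @param lengths optional per-gene lengths; adds a "tpm" assay.
#' @return the study with a "cpm" (and optionally "tpm") assay.
#' @export
normalizeStudy <- function(study, lengths = NULL) {
    cts <- SummarizedExperiment::assay(study, "counts")
    SummarizedExperiment::assay(study, "cpm") <- cpmMatrix(cts)
    if (!is.null(lengths))
        SummarizedExperiment::assay(study, "tpm") <- tpmMatrix(cts, lengths)
    study
}

studyCpm <- function(study) {
    if ("cpm" %in% SummarizedExperiment::assayNames(study))
        SummarizedExperiment::assay(study, "cpm")
    else
        cpmMatrix(SummarizedExperiment::assay(study, "counts"))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Hand-rolled step-up: sort ascending, multiply by m/rank, enforce
#' monotonicity from the largest p downwards, cap at 1. Kept explicit (rather
#' than calling \code{p.adjust}) so the procedure is self-contained and
#' testable against an independent implementation.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
    m <- length(p)
    if (m == 0L) return(numeric(0))
    ord <- order(p)
    raw <- p[ord] * m / seq_len(m)
    adj <- rev(cummin(rev(raw)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[ord] <- adj
    out
}

#' Call differentially expressed genes between two sample groups
#'
#' Per gene: the log2 fold change of group-mean CPM (with a pseudo-count),
#' a two-sided Welch t-test on log2(CPM + pseudo-count), and
#' Benjamini-Hochberg FDR across all tested genes. A gene is flagged as a
#' DEG when |log2 fold change| > 1 and FDR < 0.05 (both thresholds
#' configurable). This is a deliberately simple, fully specified test on
#' normalized counts, not a negative-binomial GLM.
#'
#' @param study an [ExpressionStudy-class].
#' @param groupA,groupB character vectors of sample ids (>= 2 each).
#' @param pseudoCount added inside fold changes and log transforms
#'   (default 0.5).
#' @param lfcThreshold,fdrThreshold DEG thresholds (defaults 1 and 0.05).
#' @return data.frame: gene_id, log2_fold_change, p_value, fdr, is_deg.
#'   Fold changes are A over B.
#' @export
callDE <- function(study, groupA, groupB, pseudoCount = 0.5,
                   lfcThreshold = 1, fdrThreshold = 0.05) {
    samples <- colnames(study)
    if (!all(c(groupA, groupB) %in% samples))
        stop("unknown sample id(s) in groups")
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs >= 2 replicates")
    cpm <- studyCpm(study)
    a <- cpm[, groupA, drop = FALSE]
    b <- cpm[, groupB, drop = FALSE]
    lfc <- log2((rowMeans(a) + pseudoCount) / (rowMeans(b) + pseudoCount))

    la <- log2(a + pseudoCount)
    lb <- log2(b + pseudoCount)
    p <- welchP(la, lb)
    fdr <- bhAdjust(p)
    data.frame(gene_id = rownames(cpm),
               log2_fold_change = lfc, p_value = p, fdr = fdr,
               is_deg = abs(lfc) > lfcThreshold & fdr < fdrThreshold,
               row.names = NULL, stringsAsFactors = FALSE)
}

# row-wise two-sided Welch t-test p-values
welchP <- function(a, b) {
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1L)
    vb <- rowSums((b - mb)^2) / (nb - 1L)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    # degenerate rows: no variance in either group
    flat <- se2 == 0
    p[flat & ma == mb] <- 1
    p[flat & ma != mb] <- 0
    p
}

#' Build a gene-to-family lookup from an orthogroup set
#'
#' @param og an [OrthogroupSet-class].
#' @return named character vector mapping gene_id to family_id.
#' @export
geneFamilyMap <- function(og) {
    fams <- rep(names(og@members),
                vapply(og@members, function(m)
                    length(unlist(m, use.names = FALSE)), integer(1)))
    stats::setNames(fams, unlist(og@members, use.names = FALSE))
}

#' Expression profile by pan-genome category
#'
#' Per-gene mean CPM within one tissue, summarized per category (n, median,
#' quartiles) with one omnibus Kruskal-Wallis test across the categories.
#' Genes not mapping to a classified family are excluded and counted.
#'
#' @param study a normalized [ExpressionStudy-class].
#' @param classification a [FamilyClassification-class].
#' @param geneFamily named character vector gene_id -> family_id
#'   (see [geneFamilyMap()]).
#' @param tissue "mycelium" or "fruiting_body".
#' @return list: \code{profile} (per-category data.frame),
#'   \code{kruskal_p}, \code{kruskal_stat}, \code{n_unmapped}.
#' @export
categoryExpressionProfile <- function(study, classification, geneFamily,
                                      tissue = c("mycelium", "fruiting_body")) {
    tissue <- match.arg(tissue)
    cpm <- studyCpm(study)
    sel <- SummarizedExperiment::colData(study)$tissue == tissue
    if (!any(sel)) stop("no samples for tissue ", tissue)
    expr <- rowMeans(cpm[, sel, drop = FALSE])

    fam <- geneFamily[rownames(cpm)]
    cat_ <- familyCategories(classification)[fam]
    keep <- !is.na(cat_)
    n_unmapped <- sum(!keep)
    expr <- expr[keep]; cat_ <- droplevels(cat_[keep])
    if (nlevels(cat_) < nlevels(familyCategories(classification)))
        warning("categor(ies) with zero genes omitted from the omnibus test")

    profile <- do.call(rbind, lapply(levels(cat_), function(lv) {
        x <- expr[cat_ == lv]
        data.frame(category = lv, n = length(x),
                   q1 = stats::quantile(x, 0.25, names = FALSE),
                   median = stats::median(x),
                   q3 = stats::quantile(x, 0.75, names = FALSE),
                   mean = mean(x), stringsAsFactors = FALSE)
    }))
    if (nlevels(cat_) >= 2L && stats::var(expr) > 0) {
        kw <- stats::kruskal.test(expr, cat_)
        kp <- kw$p.value; ks <- unname(kw$statistic)
    } else {
        kp <- 1; ks <- 0
    }
    list(profile = profile, kruskal_p = kp, kruskal_stat = ks,
         n_unmapped = n_unmapped)
}

#' Single-copy homolog groups across a genome subset
#'
#' Families with exactly one member gene in each of the requested genomes.
#'
#' @param og an [OrthogroupSet-class].
#' @param genomes genome ids (default: all genomes of the set).
#' @return data.frame with family_id and one gene-id column per genome.
#' @export
singleCopyHomologs <- function(og, genomes = genomeIDs(og)) {
    stopifnot(all(genomes %in% genomeIDs(og)))
    keep <- vapply(og@members, function(m)
        all(lengths(m[genomes]) == 1L), logical(1))
    fams <- names(og@members)[keep]
    cols <- lapply(genomes, function(g)
        vapply(og@members[keep], function(m) m[[g]], character(1)))
    out <- data.frame(family_id = fams, cols, stringsAsFactors = FALSE,
                      row.names = NULL)
    colnames(out) <- c("family_id", genomes)
    out
}

#' Homolog-group count matrix
#'
#' Rebases a per-gene count matrix onto homolog groups so that cross-genome
#' comparisons align: for a sample from genome g, a group's value is the
#' count of that group's member gene in g.
#'
#' @param study an [ExpressionStudy-class].
#' @param homologs data.frame from [singleCopyHomologs()].
#' @return an [ExpressionStudy-class] with one row per homolog group.
#' @export
homologCountMatrix <- function(study, homologs) {
    cts <- SummarizedExperiment::assay(study, "counts")
    cd <- SummarizedExperiment::colData(study)
    genomes <- setdiff(colnames(homologs), "family_id")
    if (!all(cd$genome_id %in% genomes))
        stop("study contains samples from genomes absent in homolog table")
    m <- matrix(0L, nrow(homologs), ncol(cts),
                dimnames = list(homologs$family_id, colnames(cts)))
    for (g in genomes) {
        cols <- which(cd$genome_id == g)
        if (!length(cols)) next
        genes <- homologs[[g]]
        if (!all(genes %in% rownames(cts)))
            stop("homolog gene(s) missing from count matrix for genome ", g)
        m[, cols] <- cts[genes, cols, drop = FALSE]
    }
    sheet <- data.frame(sample_id = colnames(cts),
                        as.data.frame(cd), stringsAsFactors = FALSE,
                        row.names = NULL)
    ExpressionStudy(m, sheet[, c("sample_id", "genome_id", "tissue",
                                 "replicate")])
}

#' Expression breadth across genomes
#'
#' For each homolog group, the number of genomes in which the member gene's
#' mean CPM (over replicates of one tissue) reaches a threshold.
#'
#' @param study a normalized [ExpressionStudy-class] covering the genomes.
#' @param homologs data.frame from [singleCopyHomologs()].
#' @param tissue tissue to profile.
#' @param threshold CPM threshold (> 0; default 1).
#' @return data.frame: family_id, breadth (0..number of genomes).
#' @export
expressionBreadth <- function(study, homologs,
                              tissue = c("mycelium", "fruiting_body"),
                              threshold = 1) {
    tissue <- match.arg(tissue)
    stopifnot(threshold > 0)
    cpm <- studyCpm(study)
    cd <- SummarizedExperiment::colData(study)
    genomes <- setdiff(colnames(homologs), "family_id")
    expressed <- sapply(genomes, function(g) {
        cols <- cd$genome_id == g & cd$tissue == tissue
        if (!any(cols)) return(rep(FALSE, nrow(homologs)))
        rowMeans(cpm[homologs[[g]], cols, drop = FALSE]) >= threshold
    })
    data.frame(family_id = homologs$family_id,
               breadth = as.integer(rowSums(expressed)),
               stringsAsFactors = FALSE)
}

#' Association between SV-affected homologs and differential expression
#'
#' Cross-tabulates homolog groups by {SV-affected, not} x {DEG, not} and
#' tests independence with Pearson's chi-square (continuity-corrected).
#' When any margin is zero the chi-square is undefined and Fisher's exact
#' test is substituted (noted in \code{method}).
#'
#' @param svAffected,isDeg logical vectors over the same homolog groups.
#' @return list: \code{table} (2x2), \code{proportions} (DEG rate among
#'   SV-affected vs not), \code{statistic}, \code{p_value}, \code{method}.
#' @export
svDegAssociation <- function(svAffected, isDeg) {
    stopifnot(length(svAffected) == length(isDeg),
              is.logical(svAffected), is.logical(isDeg))
    tab <- table(factor(svAffected, levels = c(TRUE, FALSE)),
                 factor(isDeg, levels = c(TRUE, FALSE)),
                 dnn = c("sv_affected", "deg"))
    margins_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    if (margins_ok) {
        ht <- stats::chisq.test(tab, correct = TRUE)
        method <- "chisq"
        statistic <- unname(ht$statistic)
    } else {
        ht <- stats::fisher.test(tab)
        method <- "fisher"
        statistic <- NA_real_
    }
    prop <- c(sv_affected = tab["TRUE", "TRUE"] / sum(tab["TRUE", ]),
              not_affected = tab["FALSE", "TRUE"] / sum(tab["FALSE", ]))
    list(table = tab, proportions = prop, statistic = statistic,
         p_value = ht$p.value, method = method)
}

#' Sporulation ratio
#'
#' Spore yield as a percentage of fruiting-body dry weight. Some strains
#' produce too little spore powder to collect; a non-positive weight is an
#' error rather than a silent 0/Inf.
#'
#' @param sporeYield_g spore yield in grams (> 0).
#' @param fruitingDryWeight_g fruiting-body dry weight in grams (> 0).
#' @return percentage.
#' @examples sporulationRatio(50, 100)  # 50
#' @export
sporulationRatio <- function(sporeYield_g, fruitingDryWeight_g) {
    if (any(sporeYield_g <= 0) || any(fruitingDryWeight_g <= 0))
        stop("weights must be positive (spore content may be too low to collect)")
    100 * sporeYield_g / fruitingDryWeight_g
}
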