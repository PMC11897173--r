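#' Read a sample sheet
#'
#' Four-column TSV: sample_id, genome_id, tissue (mycelium / fruiting_body),
#' replicate. Uniqueness of (genome_id, tissue, replicate) is enforced when
#' the sheet is combined with counts into an [ExpressionStudy-class].
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
readSampleSheet <- function(path) {
    sheet <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
    need <- c("sample_id", "genome_id", "tissue", "replicate")
    if (!all(need %in% colnames(sheet)))
        stop("sample sheet must have columns: ", paste(need, collapse = ", "))
    if (!all(sheet$tissue %in% TISSUE_LEVELS))
        stop("tissue must be one of: ", paste(TISSUE_LEVELS, collapse = ", "))
    if (anyDuplicated(sheet$sample_id))
        stop("duplicate sample_id in sheet")
    sheet
}

#' Write a sample sheet
#' @param sheet data.frame as from [readSampleSheet()].
#' @param path output path.
#' @export
writeSampleSheet <- function(sheet, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceComment("writeSampleSheet"), con)
    utils::write.table(sheet, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a count matrix and assemble an expression study
#'
#' The TSV's first column is gene_id; remaining columns are sample ids that
#' must each appear in the sheet. Counts must be non-negative integers.
#' All-zero gene rows are retained and flagged in
#' \code{rowData()$all_zero}.
#'
#' @param path path to the counts TSV.
#' @param sheet sample sheet data.frame (see [readSampleSheet()]).
#' @return an [ExpressionStudy-class].
#' @export
readCounts <- function(path, sheet) {
    tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- tab[[1L]]
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- genes
    missing <- setdiff(colnames(m), sheet$sample_id)
    if (length(missing))
        stop("sample(s) in count matrix absent from sheet: ",
             paste(missing, collapse = ", "))
    if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers")
    storage.mode(m) <- "integer"
    ExpressionStudy(m, sheet[match(colnames(m), sheet$sample_id), ])
}

#' Construct an ExpressionStudy from a count matrix and sample sheet
#'
#' @param counts gene x sample integer matrix with dimnames.
#' @param sheet sample sheet rows matching the matrix columns (by sample_id).
#' @return an [ExpressionStudy-class]; \code{rowData()$all_zero} flags genes
#'   unexpressed everywhere.
#' @export
ExpressionStudy <- function(counts, sheet) {
    stopifnot(identical(colnames(counts), sheet$sample_id))
    cd <- DataFrame(sheet[, setdiff(colnames(sheet), "sample_id"),
                          drop = FALSE],
                    row.names = sheet$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    SummarizedExperiment::rowData(se)$all_zero <- unname(rowSums(counts) == 0L)
    new("ExpressionStudy", se)
}

#' Write a count matrix
#' @param study an [ExpressionStudy-class].
#' @param path output path.
#' @export
writeCounts <- function(study, path) {
    m <- SummarizedExperiment::assay(study, "counts")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceComment("writeCounts"), con)
    utils::write.table(
        data.frame(gene_id = rownames(m), m, check.names = FALSE),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene-to-GO-term associations
#'
#' Two-column TSV (gene_id, semicolon-separated GO ids). Term sets are
#' deduplicated; malformed GO identifiers (not GO: followed by 7 digits) are
#' a format error reporting the line number.
#'
#' @param path path to the TSV.
#' @return named list gene_id -> character vector of GO term ids.
#' @export
readGoAssociations <- function(path) {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineno <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    genes <- vapply(parts, `[`, character(1), 1L)
    terms <- lapply(seq_along(parts), function(i) {
        cell <- if (length(parts[[i]]) >= 2L) parts[[i]][2L] else ""
        tt <- trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
        tt <- tt[nzchar(tt)]
        bad <- !grepl("^GO:[0-9]{7}$", tt)
        if (any(bad))
            stop(sprintf("malformed GO id '%s' at line %d",
                         tt[bad][1L], lineno[i]))
        unique(tt)
    })
    names(terms) <- genes
    terms
}

#' Write gene-to-GO-term associations
#' @param assoc named list gene_id -> GO term ids.
#' @param path output path.
#' @export
writeGoAssociations <- function(assoc, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceComment("writeGoAssociations"), con)
    writeLines(sprintf("%s\t%s", names(assoc),
                       vapply(assoc, paste, character(1), collapse = ";")),
               con)
    invisible(path)
}
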