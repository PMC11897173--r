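#' Read structural-variant calls from a VCF file
#'
#' Consumes the SV dialect exported by whole-genome-alignment callers: records
#' with an SVTYPE info key in INS/DEL/DUP/INV/TRA/BND and END and/or SVLEN.
#' Parsing is delegated to \pkg{VariantAnnotation}; this function validates
#' and converts to interval form.
#'
#' Spanning types (DEL/DUP/INV) become ranges covering the affected bases
#' (VCF POS is the padding base before the event, so the range is
#' \code{[POS+1, END]}). Insertions and translocation breakends become
#' width-1 anchor ranges at POS; their extent is carried in \code{svLength}.
#' Records without a usable SVTYPE (or insertions without SVLEN) are skipped
#' with a warning; the skip count is recorded in \code{metadata()$n_skipped}.
#'
#' @param path path to a VCF 4.x file.
#' @return a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{sv_id}, \code{svtype} and \code{svLength}.
#' @export
readSvVcf <- function(path) {
    stopifnot(file.exists(path))
    vcf <- VariantAnnotation::readVcf(path)
    inf <- VariantAnnotation::info(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    n <- length(rr)
    pos <- GenomicRanges::start(rr)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    ids <- names(rr)
    if (is.null(ids)) ids <- paste0("sv", seq_len(n))

    first_int <- function(x) {
        if (is.null(x)) return(rep(NA_integer_, n))
        if (is.list(x) || inherits(x, "List"))
            x <- vapply(x, function(v)
                if (length(v)) as.integer(v[[1L]]) else NA_integer_, integer(1))
        as.integer(x)
    }
    svtype <- if ("SVTYPE" %in% colnames(inf))
        as.character(inf$SVTYPE) else rep(NA_character_, n)
    svtype[svtype %in% "BND"] <- "TRA"
    end_ <- first_int(if ("END" %in% colnames(inf)) inf$END else NULL)
    svlen <- abs(first_int(if ("SVLEN" %in% colnames(inf)) inf$SVLEN else NULL))

    keep <- !is.na(svtype) & svtype %in% SVTYPE_LEVELS
    keep[svtype %in% "INS" & is.na(svlen)] <- FALSE
    n_skipped <- sum(!keep)
    if (n_skipped > 0L)
        warning(sprintf("skipped %d SV record(s) without usable SVTYPE/SVLEN",
                        n_skipped))

    span <- svtype %in% c("DEL", "DUP", "INV") & keep
    if (any(span)) {
        miss_end <- span & is.na(end_)
        end_[miss_end] <- pos[miss_end] + svlen[miss_end]
        if (any(span & is.na(end_)))
            stop("spanning SV without END or SVLEN")
        bad <- span & end_ < pos
        if (any(bad))
            stop(sprintf("END < POS for record(s): %s",
                         paste(ids[bad], collapse = ", ")))
    }

    start_out <- ifelse(span, pos + 1L, pos)
    end_out <- ifelse(span, end_, pos)
    len <- ifelse(span, end_out - start_out + 1L,
                  ifelse(svtype == "TRA", 1L, svlen))

    out <- GRanges(chrom[keep],
                   IRanges(start_out[keep], end_out[keep]),
                   sv_id = ids[keep],
                   svtype = factor(svtype[keep], levels = SVTYPE_LEVELS),
                   svLength = as.integer(len[keep]))
    S4Vectors::metadata(out)$n_skipped <- n_skipped
    out
}

#' Write structural variants to VCF
#'
#' Emits the symbolic-allele SV dialect [readSvVcf()] consumes (SVTYPE, END,
#' SVLEN info keys); round-trips exactly.
#'
#' @param sv a GRanges as returned by [readSvVcf()].
#' @param path output path.
#' @export
writeSvVcf <- function(sv, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        sub("^#", "##source=", provenanceComment("writeSvVcf")),
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
        "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
        paste0("##contig=<ID=",
               unique(as.character(GenomicRanges::seqnames(sv))), ">"),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (length(sv)) {
        svtype <- as.character(sv$svtype)
        span <- svtype %in% c("DEL", "DUP", "INV")
        pos <- ifelse(span, GenomicRanges::start(sv) - 1L,
                      GenomicRanges::start(sv))
        info <- ifelse(span,
                       sprintf("SVTYPE=%s;END=%d;SVLEN=%d", svtype,
                               GenomicRanges::end(sv), sv$svLength),
                       sprintf("SVTYPE=%s;SVLEN=%d", svtype, sv$svLength))
        writeLines(sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
                           as.character(GenomicRanges::seqnames(sv)), pos,
                           sv$sv_id, svtype, info), con)
    }
    invisible(path)
}
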