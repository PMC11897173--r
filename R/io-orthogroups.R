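#' Read an orthogroup membership table
#'
#' Parses the tab-separated orthogroup dialect written by orthology inference
#' tools: a header row naming the genomes, then one family per row with a
#' comma-space-separated list of member gene ids per genome cell (empty cells
#' allowed). Leading lines starting with '#' are skipped.
#'
#' @param path path to the TSV file.
#' @return an [OrthogroupSet-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Orthogroup\tA\tB", "OG1\tg1, g2\tg3", "OG2\t\tg4"), tf)
#' og <- readOrthogroups(tf)
#' familyIDs(og)
#' @export
readOrthogroups <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) < 1L)
        stop("orthogroup table: no header line found")
    cells <- strsplit(lines, "\t", fixed = TRUE)
    header <- cells[[1L]]
    if (length(header) < 2L)
        stop("orthogroup table: header must have a family column and >= 1 genome")
    genomes <- header[-1L]
    rows <- cells[-1L]
    rows <- rows[lengths(rows) > 0L]
    fam_ids <- vapply(rows, `[`, character(1), 1L)
    if (anyDuplicated(fam_ids))
        stop(sprintf("duplicate family id(s): %s",
                     paste(unique(fam_ids[duplicated(fam_ids)]), collapse = ", ")))
    members <- lapply(rows, function(r) {
        r <- c(r, rep("", length(header)))[seq_along(header)][-1L]
        m <- lapply(r, function(cell) {
            g <- strsplit(cell, ",", fixed = TRUE)[[1L]]
            g <- trimws(g)
            g[nzchar(g)]
        })
        names(m) <- genomes
        m
    })
    names(members) <- fam_ids
    new("OrthogroupSet", members = members, genomes = genomes)
}

#' Write an orthogroup membership table
#'
#' Emits the same TSV dialect [readOrthogroups()] consumes, preceded by a
#' commented provenance line. Round-trips exactly.
#'
#' @param x an [OrthogroupSet-class].
#' @param path output path.
#' @export
writeOrthogroups <- function(x, path) {
    stopifnot(is(x, "OrthogroupSet"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceComment("writeOrthogroups"), con)
    writeLines(paste(c("Orthogroup", x@genomes), collapse = "\t"), con)
    for (fam in names(x@members)) {
        m <- x@members[[fam]][x@genomes]
        cells <- vapply(m, paste, character(1), collapse = ", ")
        writeLines(paste(c(fam, cells), collapse = "\t"), con)
    }
    invisible(path)
}

provenanceComment <- function(fun, params = "") {
    ver <- tryCatch(as.character(utils::packageVersion("pangene")),
                    error = function(e) "dev")
    sprintf("# pangene %s :: %s%s", ver, fun,
            if (nzchar(params)) paste0(" ", params) else "")
}
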