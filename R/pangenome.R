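#' Build a family x genome gene-count matrix
#'
#' Collapses an [OrthogroupSet-class] into the occupancy substrate used by
#' classification, rarefaction and shared-pattern counting. Rows are ordered
#' by family id.
#'
#' @param og an [OrthogroupSet-class].
#' @return an [OrthogroupMatrix-class].
#' @export
orthogroupMatrix <- function(og) {
    stopifnot(is(og, "OrthogroupSet"))
    if (length(og@members) == 0L) stop("empty orthogroup collection")
    fams <- sort(names(og@members))
    m <- vapply(fams, function(f)
        lengths(og@members[[f]][og@genomes]), integer(length(og@genomes)))
    m <- t(m)
    dimnames(m) <- list(fams, og@genomes)
    new("OrthogroupMatrix", geneCount = m)
}

#' Occupancy-band classification scheme
#'
#' \code{defaultScheme(n)} builds the standard band layout for an n-genome
#' panel: core = families in all n genomes, softcore = n-2..n-1, dispensable
#' = 2..n-3, private = exactly 1. For n < 5 the softcore lower bound clamps
#' at 2 (the dispensable band empties first, then softcore), so small panels
#' degrade gracefully instead of erroring.
#'
#' @param nGenomes panel size (>= 2).
#' @param softcoreMin minimum occupancy counted as softcore; default
#'   \code{max(nGenomes - 2, 2)}.
#' @return a [CategoryScheme-class].
#' @examples
#' defaultScheme(15)  # core 15, softcore 13-14, dispensable 2-12, private 1
#' @export
defaultScheme <- function(nGenomes, softcoreMin = max(nGenomes - 2L, 2L)) {
    nGenomes <- as.integer(nGenomes)
    new("CategoryScheme", nGenomes = nGenomes, coreMin = nGenomes,
        softcoreMin = as.integer(min(softcoreMin, nGenomes)))
}

#' Classify families by genome occupancy
#'
#' Labels every family core / softcore / dispensable / private according to
#' the scheme's occupancy bands. Genes that fell outside the family analysis
#' altogether ("singletons") are carried alongside as private units but kept
#' in a separate tally, never merged into the private-family count.
#'
#' @param mat an [OrthogroupMatrix-class].
#' @param scheme a [CategoryScheme-class]; defaults to
#'   \code{defaultScheme(ncol)}.
#' @param singletons character vector of gene ids outside any family.
#' @return a [FamilyClassification-class].
#' @export
classifyFamilies <- function(mat, scheme = defaultScheme(length(genomeIDs(mat))),
                             singletons = character()) {
    stopifnot(is(mat, "OrthogroupMatrix"), is(scheme, "CategoryScheme"))
    if (scheme@nGenomes != length(genomeIDs(mat)))
        stop(sprintf("scheme is for %d genomes but matrix has %d",
                     scheme@nGenomes, length(genomeIDs(mat))))
    occ <- occupancy(mat)
    cat_ <- classifyOccupancy(occ, scheme)
    names(cat_) <- names(occ)
    new("FamilyClassification", category = cat_, occupancy = occ,
        scheme = scheme, singletons = as.character(singletons))
}

# the band rule itself; pure function of occupancy and scheme
classifyOccupancy <- function(occ, scheme) {
    lab <- ifelse(occ >= scheme@coreMin, "core",
           ifelse(occ >= scheme@softcoreMin, "softcore",
           ifelse(occ >= 2L, "dispensable", "private")))
    factor(lab, levels = CATEGORY_LEVELS)
}

#' Pan/core rarefaction by genome-order permutation
#'
#' Draws random orderings of the genomes (or enumerates all orderings when
#' \code{method = "exhaustive"}) and, for each ordering, records the
#' cumulative pan-genome size (families present in at least one of the first
#' k genomes) and core size (families present in all first k) for k = 1..N.
#' Orderings are sampled independently with a single seeded generator and may
#' repeat; this is sampling of genome orderings, not bootstrap resampling of
#' genomes.
#'
#' @param mat an [OrthogroupMatrix-class].
#' @param nPerm number of sampled orderings (>= 1); ignored when exhaustive.
#' @param seed integer seed for the sampling method.
#' @param method "sample" (default) or "exhaustive" (all N! orderings,
#'   N <= 8).
#' @return a [RarefactionResult-class].
#' @export
rarefy <- function(mat, nPerm = 100L, seed = 1L,
                   method = c("sample", "exhaustive")) {
    stopifnot(is(mat, "OrthogroupMatrix"))
    method <- match.arg(method)
    presence <- geneCount(mat) > 0
    n <- ncol(presence)
    if (method == "sample") {
        if (nPerm < 1L) stop("nPerm must be >= 1")
        perms <- withr::with_seed(seed, replicate(nPerm, sample.int(n),
                                                  simplify = FALSE))
    } else {
        if (n > 8L) stop("exhaustive enumeration limited to N <= 8 genomes")
        perms <- permutationsAll(n)
        seed <- NA_integer_
    }
    curves <- lapply(perms, rarefyOneOrdering, presence = presence)
    pan <- do.call(rbind, lapply(curves, `[[`, "pan"))
    core <- do.call(rbind, lapply(curves, `[[`, "core"))
    colnames(pan) <- colnames(core) <- as.character(seq_len(n))
    new("RarefactionResult", pan = pan, core = core, method = method,
        seed = as.integer(seed))
}

# cumulative pan/core along one genome ordering, O(F) via first-presence /
# first-absence positions
rarefyOneOrdering <- function(ord, presence) {
    p <- presence[, ord, drop = FALSE]
    n <- ncol(p); nf <- nrow(p)
    firstPresent <- max.col(p, ties.method = "first")
    absent <- !p
    anyAbsent <- rowSums(absent) > 0L
    firstAbsent <- rep.int(n + 1L, nf)
    if (any(anyAbsent))
        firstAbsent[anyAbsent] <- max.col(absent[anyAbsent, , drop = FALSE],
                                          ties.method = "first")
    list(pan = cumsum(tabulate(firstPresent, nbins = n)),
         core = nf - cumsum(tabulate(firstAbsent, nbins = n)))
}

permutationsAll <- function(n) {
    if (n == 1L) return(list(1L))
    sub <- permutationsAll(n - 1L)
    out <- vector("list", n * length(sub))
    i <- 0L
    for (k in seq_len(n)) for (s in sub) {
        i <- i + 1L
        out[[i]] <- c(k, ifelse(s >= k, s + 1L, s))
    }
    out
}

#' Presence/absence pattern counts over a genome subset
#'
#' Restricted to families present in at least one genome of the subset,
#' counts every presence/absence pattern (Venn cell). Pattern keys are
#' strings of 0/1 in subset order, e.g. \code{"11111"} for families shared
#' by all five genomes.
#'
#' @param mat an [OrthogroupMatrix-class].
#' @param genomes character vector of 2..6 genome ids from the matrix.
#' @return named integer vector of pattern counts.
#' @examples
#' \dontrun{sharedPatternCounts(mat, c("S1","S2","S3","S4","S6"))["11111"]}
#' @export
sharedPatternCounts <- function(mat, genomes) {
    stopifnot(is(mat, "OrthogroupMatrix"))
    unknown <- setdiff(genomes, genomeIDs(mat))
    if (length(unknown))
        stop("unknown genome id(s): ", paste(unknown, collapse = ", "))
    if (length(genomes) < 2L || length(genomes) > 6L)
        stop("subset size must be between 2 and 6")
    p <- geneCount(mat)[, genomes, drop = FALSE] > 0
    p <- p[rowSums(p) > 0L, , drop = FALSE]
    pat <- apply(p, 1L, function(r) paste(as.integer(r), collapse = ""))
    tab <- table(pat)
    stats::setNames(as.integer(tab), names(tab))
}
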