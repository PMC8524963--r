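## Derivation of putative critical regions (pCRs) from multi-source
## enhancer catalogs: deduplication, maximal source-overlap-depth runs,
## length / TSS-proximity / read-coverage filters.

#' Deduplicate a source-labelled enhancer catalog
#'
#' Removes records with identical coordinates *within* one source; the same
#' coordinates reported by two different sources are both kept (they
#' contribute overlap depth 2 during pCR derivation).
#'
#' @param enhancers GRanges with a `source` metadata column.
#' @return GRanges with at most one record per (chrom, start, end, source).
#' @export
deduplicateEnhancers <- function(enhancers) {
    if (is.null(enhancers$source) || any(enhancers$source == ""))
        stop("enhancers need a non-empty 'source' metadata column")
    key <- paste(seqnames(enhancers), start(enhancers), end(enhancers),
                 enhancers$source)
    enhancers[!duplicated(key)]
}

#' Derive putative critical regions (pCRs)
#'
#' Within each merged cluster of overlapping enhancers, counts the number of
#' *distinct sources* covering every base and extracts the maximal
#' contiguous run(s) of maximal source depth; clusters supported by a single
#' source contribute the (merged) single-source region itself. Candidates
#' with length outside `[minLen, maxLen]` are dropped.
#'
#' @param enhancers deduplicated GRanges with `source` column (see
#'   [deduplicateEnhancers()]).
#' @param minLen,maxLen inclusive length bounds (defaults 50 and 1000 bp).
#' @return sorted, non-overlapping GRanges with metadata columns `id`,
#'   `n_sources` (maximal distinct-source depth) and `singleton`.
#' @examples
#' enh <- gi("chr1", c(100, 200), c(300, 400), source = c("A", "B"))
#' derivePCRs(enh)
#' @export
derivePCRs <- function(enhancers, minLen = 50L, maxLen = 1000L) {
    if (minLen > maxLen) stop("minLen must not exceed maxLen")
    if (is.null(enhancers$source))
        stop("enhancers need a 'source' metadata column")
    ## depth counts distinct sources: collapse each source to its union first
    bySource <- lapply(split(enhancers, enhancers$source), mergeIntervals)
    flat <- unlist(GenomicRanges::GRangesList(lapply(bySource, granges)),
                   use.names = FALSE)
    runs <- coverageRuns(flat)
    clusters <- mergeIntervals(flat)
    hit <- findOverlaps(runs, clusters, ignore.strand = TRUE)
    clusterOf <- rep(NA_integer_, length(runs))
    clusterOf[queryHits(hit)] <- subjectHits(hit)
    maxDepth <- tapply(runs$depth, clusterOf, max)
    keepMulti <- runs$depth >= 2L &
        runs$depth == maxDepth[as.character(clusterOf)]
    cand <- runs[keepMulti]
    mcols(cand)$n_sources <- cand$depth
    mcols(cand)$depth <- NULL
    singles <- clusters[maxDepth == 1L]
    if (length(singles)) {
        mcols(singles)$n_sources <- 1L
        cand <- c(cand, singles)
    }
    mcols(cand)$singleton <- cand$n_sources == 1L
    cand <- sort(cand)
    cand <- cand[width(cand) >= minLen & width(cand) <= maxLen]
    mcols(cand)$id <- sprintf("pCR_%05d", seq_along(cand))
    mcols(cand) <- mcols(cand)[, c("id", "n_sources", "singleton")]
    names(cand) <- cand$id
    cand
}

#' Remove pCRs near transcription start sites
#'
#' Drops any pCR overlapping a strand-oriented promoter window around a
#' gene TSS: `upstream` bases 5' of the TSS and `downstream` bases 3' of it
#' (orientation reversed on the minus strand).
#'
#' @param pcrs GRanges of pCRs.
#' @param genes gene annotation `data.frame` (see [tssRanges()]) or a
#'   stranded one-base GRanges of TSS positions.
#' @param upstream,downstream window extents in bases (defaults 2000/1000).
#' @return the retained pCRs.
#' @export
excludeTssProximal <- function(pcrs, genes, upstream = 2000L,
                               downstream = 1000L) {
    tss <- if (is(genes, "GRanges")) genes else tssRanges(genes)
    if (any(strand(tss) == "*"))
        stop("TSS ranges must be stranded (+/-)")
    win <- suppressWarnings(promoters(tss, upstream = upstream,
                                      downstream = downstream))
    win <- GenomicRanges::restrict(win, start = 1L)
    subsetByOverlaps(pcrs, win, invert = TRUE, ignore.strand = TRUE)
}

#' Filter pCRs by minimal epigenome read coverage
#'
#' Retains a pCR iff it has at least `minReads` reads in at least
#' `minSamples` samples (the "sufficient epigenome coverage" rule).
#'
#' @param pcrs GRanges of pCRs with `id` column (or names).
#' @param counts count matrix (or [EnhancerCounts-class]) with rows indexed
#'   by pCR id; every pCR must be present.
#' @param minReads,minSamples thresholds (defaults 10 and 2).
#' @return the retained pCRs.
#' @export
filterMinCoverage <- function(pcrs, counts, minReads = 10L, minSamples = 2L) {
    m <- if (is(counts, "EnhancerCounts")) countsMatrix(counts)
         else as.matrix(counts)
    ids <- if (!is.null(pcrs$id)) pcrs$id else names(pcrs)
    missing <- setdiff(ids, rownames(m))
    if (length(missing))
        stop("pCR id(s) absent from count matrix: ",
             paste(utils::head(missing, 10), collapse = ", "))
    ok <- rowSums(m[ids, , drop = FALSE] >= minReads) >= minSamples
    pcrs[ok]
}
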