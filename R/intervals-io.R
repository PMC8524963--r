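## Interval algebra kernel and genomic file I/O.
##
## All coordinates inside the package are BED convention: 0-based, half-open
## [start, end). GRanges objects (1-based, closed) are used as the in-memory
## container; the conversion happens once at the reader/writer boundary
## (readers subtract nothing because rtracklayer already maps BED to
## GRanges; the helper constructors below take 0-based coordinates).

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand optional strand vector ("+", "-", "*").
#' @param ... further vectors stored as metadata columns.
#' @return a [GenomicRanges::GRanges].
#' @examples
#' gi(c("chr1", "chr1"), c(100, 150), c(200, 250))
#' @export
gi <- function(chrom, start, end, strand = "*", ...) {
    validateIntervals(chrom, start, end)
    GRanges(chrom, IRanges(start = as.integer(start) + 1L,
                           end = as.integer(end)),
            strand = strand, ...)
}

#' Validate 0-based half-open interval coordinates
#'
#' Errors on the first malformed record, naming it, as required at every
#' reader boundary.
#' @inheritParams gi
#' @return invisibly `TRUE`.
#' @export
validateIntervals <- function(chrom, start, end) {
    bad <- which(!(start < end) | start < 0 | is.na(chrom) | chrom == "")
    if (length(bad)) {
        b <- bad[1L]
        stop(sprintf(
            "malformed interval at record %d: %s:%s-%s (need 0 <= start < end, non-empty chrom)",
            b, chrom[b], start[b], end[b]))
    }
    invisible(TRUE)
}

#' 0-based starts/ends of a GRanges
#'
#' @param gr a GRanges.
#' @return integer vector of 0-based starts (`bedStart`) or half-open ends
#'   (`bedEnd`).
#' @export
bedStart <- function(gr) start(gr) - 1L

#' @rdname bedStart
#' @export
bedEnd <- function(gr) end(gr)

#' Merge overlapping or nearby intervals
#'
#' Produces the disjoint, sorted union of the input intervals; intervals
#' separated by at most `minGap` bases are bridged. Abutting half-open
#' intervals (gap 0) always merge.
#'
#' @param intervals a GRanges.
#' @param minGap non-negative integer, maximal gap to bridge.
#' @return a sorted, disjoint GRanges.
#' @examples
#' mergeIntervals(gi("chr1", c(100, 150), c(200, 250)))
#' @export
mergeIntervals <- function(intervals, minGap = 0L) {
    stopifnot(minGap >= 0)
    reduce(sort(intervals), min.gapwidth = minGap + 1L,
           ignore.strand = TRUE)
}

#' Coverage depth runs of an interval set
#'
#' Partitions the union of the inputs into maximal runs of constant
#' overlap depth (the number of input intervals covering each base),
#' mirroring `genomeCoverageBed`.
#'
#' @param intervals a GRanges (may be empty).
#' @return a GRanges with metadata column `depth` (>= 1); empty input gives
#'   an empty result.
#' @examples
#' coverageRuns(gi("chr1", c(100, 200), c(300, 400)))
#' @export
coverageRuns <- function(intervals) {
    if (length(intervals) == 0L) {
        out <- GRanges()
        mcols(out)$depth <- integer()
        return(out)
    }
    cov <- coverage(intervals)
    runs <- as(cov, "GRanges")
    runs <- runs[runs$score > 0L]
    names(mcols(runs))[names(mcols(runs)) == "score"] <- "depth"
    mcols(runs)$depth <- as.integer(mcols(runs)$depth)
    unname(sort(runs))
}

#' All overlapping query/subject pairs with overlap widths
#'
#' @param query,subject GRanges.
#' @return `data.frame` with columns `queryIdx`, `subjectIdx`,
#'   `overlapWidth` (>= 1 base, half-open arithmetic: abutting intervals do
#'   not pair).
#' @export
intersectIntervals <- function(query, subject) {
    hits <- findOverlaps(query, subject, minoverlap = 1L,
                         ignore.strand = TRUE)
    ow <- width(pintersect(query[queryHits(hits)], subject[subjectHits(hits)],
                           ignore.strand = TRUE))
    data.frame(queryIdx = queryHits(hits), subjectIdx = subjectHits(hits),
               overlapWidth = ow)
}

## ---- file formats ----------------------------------------------------------

#' Read/write BED3/BED6 files
#'
#' Column 4 (`name`) carries the free-text label used throughout the
#' pipeline (source database, repeat family, cohort). Coordinates on disk
#' are BED 0-based half-open; in memory GRanges convention applies.
#'
#' @param path file path.
#' @param oneBased set `TRUE` for files whose coordinates are 1-based
#'   inclusive; they are converted at this boundary.
#' @return `readBed`: a GRanges (with `name`/`score` columns when present).
#' @export
readBed <- function(path, oneBased = FALSE) {
    gr <- rtracklayer::import(path, format = "bed")
    ## 1-based inclusive [s, e] corresponds to 0-based half-open [s-1, e):
    ## only the start moves
    if (oneBased) start(gr) <- start(gr) - 1L
    if (any(width(gr) < 1L))
        stop("malformed interval (start >= end) in ", path)
    gr
}

#' @rdname readBed
#' @param gr GRanges to write.
#' @export
writeBed <- function(gr, path) {
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' Read/write bedGraph score tracks
#'
#' @param path file path.
#' @return `readBedGraph`: GRanges with numeric `score`; records must be
#'   non-overlapping within the track.
#' @export
readBedGraph <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!all(is.finite(gr$score))) stop("non-finite score in ", path)
    if (any(countOverlaps(gr, gr) > 1L))
        stop("overlapping records in bedGraph track ", path)
    gr
}

#' @rdname readBedGraph
#' @param gr scored GRanges to write.
#' @export
writeBedGraph <- function(gr, path) {
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read/write BEDPE interaction anchor pairs
#'
#' The `name` column carries the region context (e.g. CP or GZ); `score` is
#' 1 for significant interactions.
#'
#' @param path file path.
#' @return `readBedpe`: a [S4Vectors::Pairs] of GRanges anchors.
#' @export
readBedpe <- function(path) {
    rtracklayer::import(path, format = "bedpe")
}

#' @rdname readBedpe
#' @param pairs a `Pairs` of GRanges.
#' @export
writeBedpe <- function(pairs, path) {
    rtracklayer::export(pairs, path, format = "bedpe")
    invisible(path)
}

#' Read/write tab-separated numeric matrices (counts, expression)
#'
#' First column holds row identifiers, header row holds sample identifiers.
#'
#' @param path file path.
#' @return `readCountMatrix`: a numeric matrix with dimnames.
#' @export
readCountMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
}

#' @rdname readCountMatrix
#' @param m matrix to write.
#' @param idColumn name for the identifier column.
#' @export
writeCountMatrix <- function(m, path, idColumn = "region_id") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read/write plain tab-separated tables (sample metadata, gene annotation)
#'
#' Gene tables carry columns `gene_id`, `chrom`, `tss` (0-based position of
#' the transcription start site), `strand` and `biotype`.
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
readTsv <- function(path) {
    utils::read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
}

#' @rdname readTsv
#' @param df data.frame to write.
#' @export
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' TSS point ranges from a gene annotation table
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`,
#'   `biotype`.
#' @return one-base GRanges at each TSS, strand set, with `gene_id` and
#'   `biotype` metadata. Errors when a gene lacks a +/- strand.
#' @export
tssRanges <- function(genes) {
    bad <- which(!genes$strand %in% c("+", "-"))
    if (length(bad))
        stop("gene(s) without strand: ",
             paste(genes$gene_id[bad[seq_len(min(5, length(bad)))]],
                   collapse = ", "))
    gi(genes$chrom, genes$tss, genes$tss + 1L, strand = genes$strand,
       gene_id = genes$gene_id, biotype = genes$biotype)
}
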