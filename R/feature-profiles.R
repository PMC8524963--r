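## Base-level score assignment and length-rescaled bin metaprofiles:
## regions of 50-1000 bp are cut into 10 bp bins whose indices are mapped
## to relative positions 1..100 so that differently sized enhancers become
## comparable; feature distributions are then aggregated per position.

#' Base-weighted mean track score over a region
#'
#' Bases without track coverage are excluded from the denominator; a region
#' with zero covered bases yields `NA`.
#'
#' @param regions GRanges.
#' @param track scored GRanges (non-overlapping records), e.g. from
#'   [readBedGraph()].
#' @return numeric vector, one mean per region (`NA` when uncovered).
#' @export
meanRegionScore <- function(regions, track) {
    hits <- findOverlaps(regions, track, ignore.strand = TRUE)
    w <- width(pintersect(regions[queryHits(hits)],
                          track[subjectHits(hits)], ignore.strand = TRUE))
    num <- den <- numeric(length(regions))
    v <- w * track$score[subjectHits(hits)]
    for (k in seq_along(w)) {
        i <- queryHits(hits)[k]
        num[i] <- num[i] + v[k]
        den[i] <- den[i] + w[k]
    }
    ifelse(den > 0, num / den, NA_real_)
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Cut a region into fixed-size bins with relative positions 1..100
#'
#' The region is divided into `ceiling(length/binSize)` bins of `binSize`
#' bases from its start (the last bin may be shorter). Bin `i` of `B` maps
#' to relative position `1 + round((i-1)*99/(B-1))` (half rounded away from
#' zero), so the first bin is position 1 and the last is 100; a single-bin
#' region maps to position 50.
#'
#' @param region a length-1 GRanges.
#' @param binSize bin width in bases (default 10).
#' @return GRanges of the bins with metadata columns `bin` (index) and
#'   `position` (relative position).
#' @export
rescaleBins <- function(region, binSize = 10L) {
    stopifnot(length(region) == 1L)
    len <- width(region)
    B <- ceiling(len / binSize)
    s0 <- bedStart(region) + (seq_len(B) - 1L) * binSize
    e0 <- pmin(s0 + binSize, bedEnd(region))
    pos <- if (B == 1L) 50L
           else as.integer(1 + .roundHalfUp((seq_len(B) - 1) * 99 / (B - 1)))
    gi(as.character(seqnames(region)), s0, e0, bin = seq_len(B),
       position = pos)
}

#' Per-bin track statistic for one region
#'
#' Computes, for every rescaled bin of the region, the median (scores) or
#' the sum (read-count semantics) of base-level track values.
#'
#' @param region length-1 GRanges.
#' @param track scored GRanges.
#' @param stat `"median"` of per-base values or `"sum"` of per-base values.
#' @param binSize bin width (default 10).
#' @return data.frame with `bin`, `position`, `value` (NA when a bin is
#'   uncovered and `stat = "median"`).
#' @export
binScores <- function(region, track, stat = c("median", "sum"),
                      binSize = 10L) {
    stat <- match.arg(stat)
    bins <- rescaleBins(region, binSize)
    hits <- findOverlaps(bins, track, ignore.strand = TRUE)
    ow <- pintersect(bins[queryHits(hits)], track[subjectHits(hits)],
                     ignore.strand = TRUE)
    value <- vapply(seq_along(bins), function(i) {
        k <- which(queryHits(hits) == i)
        if (!length(k)) return(if (stat == "sum") 0 else NA_real_)
        vals <- rep(track$score[subjectHits(hits)[k]], width(ow)[k])
        if (stat == "median") stats::median(vals) else sum(vals)
    }, numeric(1))
    data.frame(bin = bins$bin, position = bins$position, value = value)
}

#' Aggregate per-bin values into a relative-position metaprofile
#'
#' Bins of one region colliding on the same relative position are averaged
#' first (so long regions do not dominate positions); positions are then
#' averaged across regions, with support counts.
#'
#' @param binValues data.frame with columns `region`, `position`, `value`
#'   (e.g. row-bound outputs of [binScores()] with a `region` id column
#'   added).
#' @return data.frame with `position` (1..100), `value` (mean, `NaN` where
#'   unsupported) and `support` (number of contributing regions).
#' @export
aggregateProfile <- function(binValues) {
    if (!nrow(binValues)) stop("no regions to aggregate")
    bv <- binValues[!is.na(binValues$value), , drop = FALSE]
    key <- interaction(bv$region, bv$position, drop = TRUE)
    collapsed <- data.frame(
        region = tapply(as.character(bv$region), key, `[`, 1L),
        position = as.integer(tapply(bv$position, key, `[`, 1L)),
        value = as.numeric(tapply(bv$value, key, mean)))
    agg <- data.frame(position = 1:100, value = NaN, support = 0L)
    t1 <- tapply(collapsed$value, collapsed$position, mean)
    t2 <- tapply(collapsed$value, collapsed$position, length)
    idx <- as.integer(names(t1))
    agg$value[idx] <- as.numeric(t1)
    agg$support[idx] <- as.integer(t2)
    agg
}

#' Metaprofile of a score track over many regions
#'
#' Convenience wrapper: rescales each region into bins, computes the
#' per-bin statistic (`median` for score tracks, `log2sum` for read-count
#' tracks: `log2(1 + sum)`), and aggregates across regions.
#'
#' @param regions GRanges.
#' @param track scored GRanges.
#' @param stat `"median"` or `"log2sum"`.
#' @param binSize bin width (default 10).
#' @return see [aggregateProfile()].
#' @export
profileRegions <- function(regions, track, stat = c("median", "log2sum"),
                           binSize = 10L) {
    stat <- match.arg(stat)
    innerStat <- if (stat == "median") "median" else "sum"
    pieces <- lapply(seq_along(regions), function(i) {
        b <- binScores(regions[i], track, stat = innerStat,
                       binSize = binSize)
        b$region <- i
        b
    })
    bv <- do.call(rbind, pieces)
    if (stat == "log2sum") bv$value <- log2(1 + bv$value)
    aggregateProfile(bv)
}

#' GC-content score track computed from sequence
#'
#' Computes per-bin GC fraction over the given regions directly from a
#' FASTA file (or `DNAStringSet`), producing a scored GRanges in the same
#' shape as a precomputed GC bedGraph track, so both inputs flow through
#' the same profiling code and can be checked against each other.
#'
#' @param fasta path to a FASTA file or a [Biostrings::DNAStringSet] whose
#'   names are chromosome names.
#' @param regions GRanges to cover.
#' @param binSize bin width in bases (default 10).
#' @return GRanges with a `score` column (GC fraction per bin).
#' @export
gcTrack <- function(fasta, regions, binSize = 10L) {
    seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta)
            else fasta
    pieces <- lapply(seq_along(regions), function(i) {
        chrom <- as.character(seqnames(regions))[i]
        if (!chrom %in% names(seqs))
            stop("chromosome ", chrom, " absent from the FASTA")
        s0 <- seq(bedStart(regions)[i], bedEnd(regions)[i] - 1L,
                  by = binSize)
        e0 <- pmin(s0 + binSize, bedEnd(regions)[i])
        v <- Biostrings::Views(seqs[[chrom]], start = s0 + 1L, end = e0)
        frac <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1L]
        data.frame(chrom = chrom, start = s0, end = e0, score = frac)
    })
    df <- do.call(rbind, pieces)
    gi(df$chrom, df$start, df$end, score = unname(df$score))
}

#' Central sub-interval of a region (relative positions 40-60)
#'
#' Returns the sub-interval spanned by the rescaled bins whose relative
#' positions fall in `[40, 60]`; for regions too short for any bin to map
#' into that window, the middle bin alone is returned.
#'
#' @param region length-1 GRanges.
#' @param binSize bin width (default 10).
#' @return a length-1 GRanges.
#' @examples
#' centralSubset(gi("chr1", 0, 1000))  # chr1:390-600 (0-based)
#' @export
centralSubset <- function(region, binSize = 10L) {
    bins <- rescaleBins(region, binSize)
    sel <- which(bins$position >= 40L & bins$position <= 60L)
    if (!length(sel)) sel <- ceiling(length(bins) / 2)
    gi(as.character(seqnames(region)),
       min(bedStart(bins[sel])), max(bedEnd(bins[sel])))
}
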