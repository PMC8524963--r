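#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' Container for pCR-by-sample epigenome read counts
#'
#' `EnhancerCounts` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] with a mandatory
#' integer `counts` assay and per-sample metadata columns describing the
#' epigenome experiment design: `mark` (assay, e.g. H3K27ac or ATAC),
#' `time_point` (developmental stage label), `brain_region` (anatomical
#' label), `replicate_group` (replicate grouping, may be `NA` until
#' [groupReplicates()] assigns it) and `library_size` (total mapped reads).
#'
#' @slot .. see `RangedSummarizedExperiment`; rows are putative critical
#'   regions (pCRs), columns are epigenome samples.
#' @seealso [EnhancerCounts()] for construction, [countReads()],
#'   [runDifferentialActivity()]
#' @export
setClass("EnhancerCounts", contains = "RangedSummarizedExperiment")

.validEnhancerCounts <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    }
    need <- c("mark", "time_point", "brain_region", "replicate_group",
              "library_size")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("library_size" %in% colnames(colData(object)) &&
        any(colData(object)$library_size <= 0))
        msg <- c(msg, "library_size must be positive")
    if (length(msg)) msg else TRUE
}
setValidity("EnhancerCounts", .validEnhancerCounts)

#' Construct an EnhancerCounts object
#'
#' @param counts integer matrix, pCRs (rows) by samples (columns); row names
#'   are pCR identifiers, column names sample identifiers.
#' @param rowRanges optional [GenomicRanges::GRanges] of the pCRs (one per
#'   row). When omitted, placeholder ranges on an artificial chromosome are
#'   used so that purely tabular workflows still work.
#' @param sampleData `data.frame`/`DataFrame` with one row per sample and
#'   columns `mark`, `time_point`, `brain_region`, `replicate_group`,
#'   `library_size`. A missing `library_size` is filled with column sums; a
#'   missing `replicate_group` with `NA`.
#' @return an [EnhancerCounts-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), 5, 4,
#'             dimnames = list(paste0("pCR_", 1:5), paste0("s", 1:4)))
#' meta <- data.frame(mark = "H3K27ac", time_point = rep(c("T1", "T2"), 2),
#'                    brain_region = "cortex")
#' ec <- EnhancerCounts(m, sampleData = meta)
#' @export
EnhancerCounts <- function(counts, rowRanges = NULL, sampleData) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    sampleData <- DataFrame(sampleData)
    if (is.null(sampleData$replicate_group))
        sampleData$replicate_group <- NA_character_
    if (is.null(sampleData$library_size))
        sampleData$library_size <- colSums(counts)
    if (is.null(rowRanges)) {
        rowRanges <- GRanges("unplaced",
                             IRanges(start = seq_len(nrow(counts)) * 2000L,
                                     width = 500L))
        names(rowRanges) <- rownames(counts)
    }
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = rowRanges, colData = sampleData)
    new("EnhancerCounts", se)
}

#' @describeIn EnhancerCounts the integer count matrix.
#' @param x an `EnhancerCounts` object.
#' @export
countsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn EnhancerCounts per-sample library sizes.
#' @export
librarySizes <- function(x) colData(x)$library_size

#' Differential-activity result container
#'
#' Holds the per-region, per-analysis quasi-likelihood F-test results
#' (`calls`) and the pooled DAE/nDAE labels (`labels`). An *analysis* is one
#' epigenome mark crossed with one design factor (developmental time point
#' or brain region).
#'
#' @slot calls `DataFrame` with columns `pcr_id`, `analysis`, `F`, `p`,
#'   `fdr`, `significant`.
#' @slot labels `DataFrame` with columns `pcr_id`, `n_significant_analyses`,
#'   `label` (`"DAE"` or `"nDAE"`).
#' @slot alpha FDR threshold used.
#' @slot minAnalyses pooling threshold (label DAE iff significant in at
#'   least this many analyses).
#' @slot dispersions named numeric, common NB dispersion per analysis.
#' @export
setClass("DifferentialActivity",
         representation(calls = "DataFrame", labels = "DataFrame",
                        alpha = "numeric", minAnalyses = "integer",
                        dispersions = "numeric"))

#' @describeIn DifferentialActivity per-analysis test table.
#' @param object a `DifferentialActivity` object.
#' @export
daeCalls <- function(object) object@calls

#' @describeIn DifferentialActivity pooled per-region labels.
#' @export
daeLabels <- function(object) object@labels

setMethod("show", "DifferentialActivity", function(object) {
    tab <- table(object@labels$label)
    cat("DifferentialActivity:", nrow(object@labels), "regions,",
        length(unique(object@calls$analysis)), "analyses\n")
    cat("  DAE:", sum(object@labels$label == "DAE"),
        " nDAE:", sum(object@labels$label == "nDAE"),
        " (alpha =", object@alpha,
        ", pooling >=", object@minAnalyses, "analyses)\n")
    invisible(tab)
})

#' Two-by-two contingency analysis result
#'
#' Result of an odds-ratio / Fisher exact analysis of a 2x2 table with rows
#' as groups (e.g. case/control cohorts, DAE/nDAE) and columns as
#' overlap/no-overlap. The odds ratio is the sample cross-product ratio
#' `(a*d)/(b*c)`; when any cell is zero (and correction is `"auto"` or
#' `"always"`) the Haldane-Anscombe correction adds 0.5 to every cell before
#' forming the ratio and its confidence interval.
#'
#' @slot table the (uncorrected) integer 2x2 table.
#' @slot oddsRatio sample odds ratio on the possibly corrected cells.
#' @slot corrected whether the Haldane-Anscombe correction was applied.
#' @slot pValue two-sided Fisher exact p value (on the uncorrected table).
#' @slot confInt length-2 numeric, normal-approximation CI on the log odds
#'   ratio scale, exponentiated.
#' @export
setClass("ContingencyResult",
         representation(table = "matrix", oddsRatio = "numeric",
                        corrected = "logical", pValue = "numeric",
                        confInt = "numeric"))

setValidity("ContingencyResult", function(object) {
    if (!all(dim(object@table) == c(2L, 2L))) return("table must be 2x2")
    if (any(object@table < 0)) return("table cells must be >= 0")
    if (length(object@pValue) == 1L &&
        (object@pValue < 0 || object@pValue > 1))
        return("p value outside [0, 1]")
    TRUE
})

#' @describeIn ContingencyResult the sample odds ratio.
#' @param object a `ContingencyResult`.
#' @export
oddsRatioValue <- function(object) object@oddsRatio

#' @describeIn ContingencyResult the two-sided Fisher exact p value.
#' @export
fisherPValue <- function(object) object@pValue

#' @describeIn ContingencyResult the 95 percent confidence interval.
#' @export
confInt <- function(object) object@confInt

setMethod("show", "ContingencyResult", function(object) {
    cat("ContingencyResult (2x2)\n")
    print(object@table)
    cat(sprintf("odds ratio = %g%s, Fisher p = %g, 95%% CI [%g, %g]\n",
                object@oddsRatio,
                if (object@corrected) " (Haldane-Anscombe corrected)" else "",
                object@pValue, object@confInt[1], object@confInt[2]))
    invisible(NULL)
})
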