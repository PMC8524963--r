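## Contingency statistics (two-sided Fisher exact test, odds ratios with
## Haldane-Anscombe correction) and the transposable-element
## observed/expected enrichment.

.asTable <- function(table) {
    m <- as.matrix(table)
    if (!all(dim(m) == c(2L, 2L))) stop("a 2x2 table is required")
    if (any(m < 0) || any(m != round(m)))
        stop("table cells must be non-negative integers")
    storage.mode(m) <- "double"
    m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums, over the hypergeometric support fixed by the table margins, the
#' probabilities of all tables no more likely than the observed one (R's
#' minimum-likelihood two-sided rule, with the same 1e-7 relative slack as
#' `fisher.test`). Probabilities are computed in log space
#' (`stats::dhyper(log = TRUE)`), so totals up to 1e6 are safe.
#'
#' @param table 2x2 matrix (rows = groups, columns = overlap / no overlap)
#'   or vector `c(a, b, c, d)` row-wise.
#' @return two-sided p value.
#' @examples
#' fisherExact2x2(matrix(c(32, 143, 2, 36), 2, byrow = TRUE))  # 0.05119
#' @export
fisherExact2x2 <- function(table) {
    m <- .asTable(if (is.matrix(table)) table
                  else matrix(table, 2L, byrow = TRUE))
    a <- m[1, 1]
    r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
    support <- max(0, c1 - r2):min(r1, c1)
    logp <- stats::dhyper(support, r1, r2, c1, log = TRUE)
    logObs <- stats::dhyper(a, r1, r2, c1, log = TRUE)
    p <- sum(exp(logp[logp <= logObs + log(1 + 1e-7)]))
    min(p, 1)
}

#' Odds ratio with optional Haldane-Anscombe correction
#'
#' The sample odds ratio `(a*d)/(b*c)`. Under `correction = "auto"` 0.5 is
#' added to every cell iff any cell is zero; `"always"`/`"never"` force the
#' behaviour. The confidence interval is the normal approximation on the
#' log odds ratio, `exp(log(OR) +/- 1.96*sqrt(sum(1/cell)))`, on the
#' (possibly corrected) cells. The attached p value is the two-sided Fisher
#' exact p on the uncorrected table.
#'
#' @param table 2x2 matrix or row-wise vector `c(a, b, c, d)`.
#' @param correction `"auto"`, `"always"` or `"never"`.
#' @return a [ContingencyResult-class].
#' @examples
#' oddsRatioValue(oddsRatio(c(32, 143, 2, 36)))  # 4.027972
#' @export
oddsRatio <- function(table, correction = c("auto", "always", "never")) {
    correction <- match.arg(correction)
    m <- .asTable(if (is.matrix(table)) table
                  else matrix(table, 2L, byrow = TRUE))
    doCorrect <- switch(correction,
                        auto = any(m == 0), always = TRUE, never = FALSE)
    mc <- if (doCorrect) m + 0.5 else m
    or <- (mc[1, 1] * mc[2, 2]) / (mc[1, 2] * mc[2, 1])
    se <- sqrt(sum(1 / mc))
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
    tab <- m; storage.mode(tab) <- "integer"
    new("ContingencyResult", table = tab, oddsRatio = or,
        corrected = doCorrect, pValue = fisherExact2x2(m), confInt = ci)
}

#' Transposable-element observed/expected enrichment
#'
#' For each repeat family overlapping more than `minOverlap` regions of the
#' universe: the relative frequency `f_all = n_overlaps/n` yields the
#' expected overlap count `E = f_all * n_test` in each test set, compared
#' with the observed count `O`. A region overlapping several instances of
#' one family counts once per family. Families with `O/E > 1` are called
#' enriched, `O/E < 0.5` depleted, otherwise neutral.
#'
#' @param universe GRanges of all pCRs.
#' @param testSets named list of GRanges, each a subset of `universe`.
#' @param repeats GRanges of repeat instances with a `family` (or `name`)
#'   column.
#' @param minOverlap universe-overlap threshold; families with
#'   `n_overlaps <= minOverlap` are excluded (default 15).
#' @return data.frame with `set`, `family`, `n_overlaps`, `f_all`,
#'   `n_test`, `E`, `O`, `OE`, `call`.
#' @export
teEnrichment <- function(universe, testSets, repeats, minOverlap = 15L) {
    if (is.null(repeats$family) && !is.null(repeats$name))
        repeats$family <- repeats$name
    stopifnot(!is.null(repeats$family), is.list(testSets),
              !is.null(names(testSets)))
    ukey <- paste0(seqnames(universe), ":", start(universe), "-",
                   end(universe))
    for (nm in names(testSets)) {
        tkey <- paste0(seqnames(testSets[[nm]]), ":",
                       start(testSets[[nm]]), "-", end(testSets[[nm]]))
        if (!all(tkey %in% ukey))
            stop("test set '", nm, "' is not a subset of the universe")
    }
    n <- length(universe)
    fams <- sort(unique(repeats$family))
    out <- list()
    for (fam in fams) {
        rf <- repeats[repeats$family == fam]
        nov <- sum(overlapsAny(universe, rf, ignore.strand = TRUE))
        if (nov <= minOverlap) next
        fAll <- nov / n
        for (nm in names(testSets)) {
            ts <- testSets[[nm]]
            O <- sum(overlapsAny(ts, rf, ignore.strand = TRUE))
            E <- fAll * length(ts)
            oe <- O / E
            out[[length(out) + 1L]] <- data.frame(
                set = nm, family = fam, n_overlaps = nov, f_all = fAll,
                n_test = length(ts), E = E, O = O, OE = oe,
                call = if (oe > 1) "enriched" else if (oe < 0.5) "depleted"
                       else "neutral")
        }
    }
    if (!length(out))
        return(data.frame(set = character(), family = character(),
                          n_overlaps = integer(), f_all = numeric(),
                          n_test = integer(), E = numeric(), O = integer(),
                          OE = numeric(), call = character()))
    do.call(rbind, out)
}

#' Region-set enrichment of a feature set between two query sets
#'
#' Builds the 2x2 table of regions in each query set overlapping (by at
#' least one base, at least one feature) vs not, and delegates to
#' [oddsRatio()] / [fisherExact2x2()].
#'
#' @param queryA,queryB GRanges (e.g. DAEs and nDAEs); both non-empty.
#' @param features GRanges of features (variants, CNV intervals, GWAS
#'   loci); non-empty.
#' @return a [ContingencyResult-class].
#' @export
regionSetEnrichment <- function(queryA, queryB, features) {
    if (!length(queryA) || !length(queryB)) stop("empty query set")
    if (!length(features)) stop("empty feature set")
    a <- sum(overlapsAny(queryA, features, ignore.strand = TRUE))
    c_ <- sum(overlapsAny(queryB, features, ignore.strand = TRUE))
    oddsRatio(matrix(c(a, length(queryA) - a,
                       c_, length(queryB) - c_), 2L, byrow = TRUE))
}
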