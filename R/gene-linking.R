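## Enhancer-gene linking through significant chromatin interactions (10 kb
## anchor bins), restricted to intra-TAD pairs and protein-coding/lincRNA
## genes, plus the link-count tallies and the group-comparison statistics.

#' Link pCRs to genes via chromatin interactions
#'
#' A link is emitted when a pCR overlaps one anchor of a significant
#' interaction, a gene TSS falls in the partner anchor, the pCR midpoint
#' and the TSS lie in the same TAD of the same region context (CP/GZ), and
#' the gene biotype is protein-coding or lincRNA. Duplicate
#' (pCR, gene, context) combinations are collapsed.
#'
#' @param pcrs GRanges of pCRs with `id` column.
#' @param interactions a [S4Vectors::Pairs] of 10 kb anchor GRanges with
#'   metadata columns `context` (`"CP"`/`"GZ"`) and logical `significant`,
#'   as read by [readBedpe()] (there `name` = context, `score` 1 =
#'   significant); or a plain Pairs whose `name`/`score` are interpreted
#'   that way.
#' @param tads GRanges of TADs with a `context` column (or `name`).
#' @param genes gene annotation `data.frame` (see [tssRanges()]).
#' @param resolution declared anchor bin size; anchors of a different width
#'   trigger a warning (default 10000).
#' @param biotypes gene biotypes retained.
#' @return `DataFrame` with columns `pcr_id`, `gene_id`, `biotype`,
#'   `context`, `tad_id`.
#' @export
linkEnhancersToGenes <- function(pcrs, interactions, tads, genes,
                                 resolution = 10000L,
                                 biotypes = c("protein_coding", "lincRNA")) {
    a1 <- first(interactions); a2 <- second(interactions)
    mc <- mcols(interactions)
    context <- if (!is.null(mc$context)) mc$context else mc$name
    significant <- if (!is.null(mc$significant)) mc$significant
                   else if (!is.null(mc$score)) mc$score > 0
                   else rep(TRUE, length(interactions))
    if (any(width(a1) != resolution) || any(width(a2) != resolution))
        warning("anchor width differs from declared resolution ",
                resolution)
    keep <- which(significant)
    if (is.null(tads$context) && !is.null(tads$name))
        tads$context <- tads$name
    tss <- tssRanges(genes)
    tssOK <- tss[tss$biotype %in% biotypes]
    mid <- resize(pcrs, width = 1L, fix = "center")

    linkFrom <- function(anchorE, anchorG, intIdx) {
        he <- findOverlaps(pcrs, anchorE[intIdx], ignore.strand = TRUE)
        hg <- findOverlaps(tssOK, anchorG[intIdx], ignore.strand = TRUE)
        if (!length(he) || !length(hg)) return(NULL)
        eByInt <- split(queryHits(he), subjectHits(he))
        gByInt <- split(queryHits(hg), subjectHits(hg))
        shared <- intersect(names(eByInt), names(gByInt))
        if (!length(shared)) return(NULL)
        do.call(rbind, lapply(shared, function(s) {
            expand.grid(pcr = eByInt[[s]], gene = gByInt[[s]],
                        int = intIdx[as.integer(s)])
        }))
    }
    cand <- rbind(linkFrom(a1, a2, keep), linkFrom(a2, a1, keep))
    if (is.null(cand) || !nrow(cand))
        return(DataFrame(pcr_id = character(), gene_id = character(),
                         biotype = character(), context = character(),
                         tad_id = character()))
    ## intra-TAD filter: pCR midpoint and TSS inside one TAD of the
    ## interaction's context
    tadOfMid <- findOverlaps(mid, tads, ignore.strand = TRUE)
    tadOfTss <- findOverlaps(tssOK, tads, ignore.strand = TRUE)
    midTad <- split(subjectHits(tadOfMid), queryHits(tadOfMid))
    tssTad <- split(subjectHits(tadOfTss), queryHits(tadOfTss))
    ctx <- context[cand$int]
    rows <- lapply(seq_len(nrow(cand)), function(i) {
        tE <- midTad[[as.character(cand$pcr[i])]]
        tG <- tssTad[[as.character(cand$gene[i])]]
        common <- intersect(tE, tG)
        common <- common[tads$context[common] == ctx[i]]
        if (!length(common)) return(NULL)
        data.frame(pcr_id = pcrs$id[cand$pcr[i]],
                   gene_id = tssOK$gene_id[cand$gene[i]],
                   biotype = tssOK$biotype[cand$gene[i]],
                   context = ctx[i],
                   tad_id = paste0("TAD_", ctx[i], "_", common[1L]))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(DataFrame(pcr_id = character(), gene_id = character(),
                         biotype = character(), context = character(),
                         tad_id = character()))
    out <- out[!duplicated(out[, c("pcr_id", "gene_id", "context")]), ,
               drop = FALSE]
    DataFrame(out, row.names = NULL)
}

#' Tally link multiplicities
#'
#' Counts, per enhancer, how many genes it links to, and per gene, how many
#' enhancers link to it, with the 1/2/3/4/5+ bucketing used for reporting.
#'
#' @param links link table from [linkEnhancersToGenes()].
#' @return list with `perEnhancer` and `perGene` data.frames (columns `id`,
#'   `n`, `bucket`).
#' @export
linkCounts <- function(links) {
    links <- as.data.frame(links)
    bucket <- function(n) ifelse(n >= 5, "5+", as.character(n))
    tallies <- function(key) {
        if (!nrow(links))
            return(data.frame(id = character(), n = integer(),
                              bucket = character()))
        t <- table(links[[key]])
        data.frame(id = names(t), n = as.integer(t),
                   bucket = bucket(as.integer(t)), row.names = NULL)
    }
    list(perEnhancer = tallies("pcr_id"), perGene = tallies("gene_id"))
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when both samples have at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Identical constant samples give p = 1.
#'
#' @param x,y numeric samples (independent groups).
#' @return two-sided p value.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
rankSumTest <- function(x, y) {
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    if (length(unique(c(x, y))) == 1L) return(1)
    ties <- any(duplicated(c(x, y)))
    useExact <- length(x) <= 8L && length(y) <= 8L && !ties
    suppressWarnings(
        stats::wilcox.test(x, y, exact = useExact, correct = TRUE)$p.value)
}

#' Trajectory odds ratios between DAE- and nDAE-linked genes
#'
#' For each expression trajectory class (falling/rising/constant), forms
#' the 2x2 table of DAE-linked vs nDAE-linked genes falling in vs out of
#' the class and computes the sample odds ratio and the two-sided Fisher
#' exact p value.
#'
#' @param daeGenes,ndaeGenes character vectors of linked gene ids (each
#'   non-empty).
#' @param trajectory named character vector mapping every tested gene to
#'   its trajectory class.
#' @return `data.frame` with one row per trajectory class: counts `a`-`d`,
#'   `odds_ratio`, `p`.
#' @export
trajectoryOdds <- function(daeGenes, ndaeGenes, trajectory) {
    if (!length(daeGenes) || !length(ndaeGenes))
        stop("gene sets must be non-empty")
    genes <- unique(c(daeGenes, ndaeGenes))
    miss <- setdiff(genes, names(trajectory))
    if (length(miss))
        stop("trajectory label missing for gene(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
    res <- lapply(sort(unique(trajectory[genes])), function(tr) {
        a <- sum(trajectory[daeGenes] == tr)
        b <- length(daeGenes) - a
        c_ <- sum(trajectory[ndaeGenes] == tr)
        d <- length(ndaeGenes) - c_
        cr <- oddsRatio(matrix(c(a, b, c_, d), 2L, byrow = TRUE))
        data.frame(trajectory = tr, a = a, b = b, c = c_, d = d,
                   odds_ratio = oddsRatioValue(cr), p = fisherPValue(cr))
    })
    do.call(rbind, res)
}
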