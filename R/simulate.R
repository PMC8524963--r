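## Synthetic-data generator: emulates every pipeline input (multi-source
## enhancer calls, NB epigenome counts with planted differential regions,
## TAD/loop geometry, score tracks with central enrichment, repeat and
## variant sets with configurable enrichment) with full ground truth, so
## parameter recovery can be measured against known answers.

.streamSeed <- function(master, label) {
    h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
    as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

#' Simulation configuration
#'
#' Bundles every generator parameter with defaults chosen to mirror the
#' study conditions the pipeline is designed for: a handful of enhancer
#' sources with tens-of-bases boundary jitter, negative-binomial counts at
#' mean depth 50 with dispersion 0.05, 10 percent planted differential
#' regions with at least a 2-fold change across three developmental time
#' points in two marks, 10 kb interaction anchors inside 400 kb TADs with
#' about 80 percent intra-TAD loops, and case/control variant sets with a
#' target odds ratio of 2.
#'
#' @param seed master RNG seed (mandatory); every output draws from its own
#'   stream derived from this seed by a stable label, so adding one output
#'   never perturbs another.
#' @param genome named integer vector of chromosome lengths.
#' @param nSources number of enhancer source databases.
#' @param nTrueEnhancers number of true enhancers to plant.
#' @param jitterSd boundary jitter standard deviation in bp.
#' @param fracMultiSource fraction of true enhancers reported by >= 2
#'   sources.
#' @param marks epigenome marks simulated.
#' @param nTimePoints,repsPerGroup time points and replicates per (mark,
#'   time point).
#' @param meanDepth mean per-region read count at library factor 1.
#' @param dispersion NB dispersion phi (variance = mu + phi*mu^2).
#' @param fracDifferential fraction of regions with planted differential
#'   activity.
#' @param lfcRange magnitude range of planted log2 fold changes (applied as
#'   a linear trend across time points, same sign in all marks).
#' @param nGenes,tadSize,loopResolution,intraTadFrac linking-layer
#'   geometry.
#' @param nCaseVariants,nControlVariants,targetOR,baselineHitRate variant
#'   simulation: control variants overlap a DAE with probability
#'   `baselineHitRate`; case variants with the probability implied by
#'   `targetOR`.
#' @param bumpAmplitude,trackBaseline score-track shape (Gaussian bump on a
#'   flat background).
#' @return a classed list (`SimulationConfig`).
#' @export
simulationConfig <- function(seed,
                             genome = c(chr1 = 10000000L),
                             nSources = 4L,
                             nTrueEnhancers = 300L,
                             jitterSd = 20,
                             fracMultiSource = 0.8,
                             marks = c("H3K27ac", "ATAC"),
                             nTimePoints = 3L,
                             repsPerGroup = 2L,
                             meanDepth = 50,
                             dispersion = 0.05,
                             fracDifferential = 0.1,
                             lfcRange = c(1, 2),
                             nGenes = 200L,
                             tadSize = 400000L,
                             loopResolution = 10000L,
                             intraTadFrac = 0.8,
                             nCaseVariants = 2000L,
                             nControlVariants = 2000L,
                             targetOR = 2,
                             baselineHitRate = 0.2,
                             bumpAmplitude = 0.5,
                             trackBaseline = 0.2) {
    if (missing(seed)) stop("seed is mandatory")
    cfg <- as.list(environment())
    stopifnot(cfg$nSources >= 1, cfg$nTrueEnhancers >= 1,
              cfg$fracMultiSource >= 0, cfg$fracMultiSource <= 1,
              cfg$fracDifferential >= 0, cfg$fracDifferential <= 1,
              cfg$dispersion >= 0, cfg$meanDepth > 0,
              cfg$intraTadFrac >= 0, cfg$intraTadFrac <= 1)
    structure(cfg, class = "SimulationConfig")
}

#' Simulate multi-source enhancer catalogs
#'
#' Plants non-overlapping true enhancers, reports each through a random
#' subset of sources with normal boundary jitter (clipped to >= 50 bp),
#' leaves a configurable fraction single-source, and injects a few
#' identical duplicate records to exercise deduplication.
#'
#' @param config a [simulationConfig()].
#' @return list with `enhancers` (GRanges + `source`) and `truth` (list:
#'   `trueEnhancers` GRanges, `nSourcesPerEnhancer`).
#' @export
simulateEnhancerSources <- function(config) {
    set.seed(.streamSeed(config$seed, "enhancers"))
    chrLen <- config$genome[[1L]]
    chrom <- names(config$genome)[1L]
    n <- config$nTrueEnhancers
    lens <- round(stats::runif(n, 150, 800))
    slot <- floor(chrLen / n)
    if (slot < 1000 + max(lens)) stop("genome too small for requested count")
    starts <- (seq_len(n) - 1L) * slot +
        round(stats::runif(n, 0, slot - lens - 900))
    truth <- gi(chrom, starts, starts + lens)
    nSrc <- ifelse(stats::runif(n) < config$fracMultiSource,
                   pmin(1L + 1L + stats::rbinom(n, config$nSources - 2L, 0.5),
                        config$nSources),
                   1L)
    recs <- list()
    for (i in seq_len(n)) {
        srcs <- sample(seq_len(config$nSources), nSrc[i])
        for (s in srcs) {
            st <- starts[i] + round(stats::rnorm(1, 0, config$jitterSd))
            en <- starts[i] + lens[i] + round(stats::rnorm(1, 0,
                                                           config$jitterSd))
            st <- max(0, st)
            if (en - st < 50) en <- st + 50
            recs[[length(recs) + 1L]] <- data.frame(
                start = st, end = en, source = paste0("src", s))
        }
    }
    df <- do.call(rbind, recs)
    ## exact duplicates within a source to exercise deduplication
    dup <- df[sample(nrow(df), max(2L, round(0.02 * nrow(df)))), ]
    df <- rbind(df, dup)
    enh <- gi(chrom, df$start, df$end, source = df$source)
    list(enhancers = enh,
         truth = list(trueEnhancers = truth, nSourcesPerEnhancer = nSrc))
}

#' Simulate NB epigenome counts with planted differential regions
#'
#' Counts follow `y ~ NB(mean = depth * libFactor * rel_g * FC, phi)` with
#' region-level relative abundances `rel_g` (log-normal, mean 1) and
#' library factors uniform in `[0.5, 2]`. A `fracDifferential` subset of
#' regions gets a planted log2 fold change applied as a linear trend across
#' time points, with the same sign and magnitude in every mark (so planted
#' regions are discoverable in >= 2 analyses, as the pooled caller
#' requires).
#'
#' @param config a [simulationConfig()].
#' @param regions GRanges of regions to simulate counts for (e.g. derived
#'   pCRs or the planted truth); non-empty.
#' @return list with `counts` (an [EnhancerCounts-class]) and `truth`
#'   (logical `differential`, numeric `lfc`).
#' @export
simulateEpigenomeCounts <- function(config, regions) {
    if (!length(regions)) stop("regions must be non-empty")
    set.seed(.streamSeed(config$seed, "counts"))
    G <- length(regions)
    rel <- exp(stats::rnorm(G, 0, 0.5)); rel <- rel / mean(rel)
    diffFlag <- stats::runif(G) < config$fracDifferential
    lfc <- ifelse(diffFlag,
                  sample(c(-1, 1), G, replace = TRUE) *
                      stats::runif(G, config$lfcRange[1], config$lfcRange[2]),
                  0)
    tp <- seq_len(config$nTimePoints)
    meta <- expand.grid(rep = seq_len(config$repsPerGroup), time = tp,
                        mark = config$marks, stringsAsFactors = FALSE)
    J <- nrow(meta)
    libF <- stats::runif(J, 0.5, 2)
    counts <- matrix(0L, G, J)
    for (j in seq_len(J)) {
        ## progressive trajectory: the planted log2 fold change applies to
        ## every stage transition, so activity compounds across stages
        mu <- config$meanDepth * libF[j] * rel * 2^(lfc * (meta$time[j] - 1))
        counts[, j] <- if (config$dispersion < 1e-10) stats::rpois(G, mu)
                       else stats::rnbinom(G, size = 1 / config$dispersion,
                                           mu = mu)
    }
    ids <- if (!is.null(regions$id)) regions$id
           else sprintf("pCR_%05d", seq_len(G))
    dimnames(counts) <- list(ids, sprintf("%s_T%d_r%d", meta$mark,
                                          meta$time, meta$rep))
    sd <- data.frame(mark = meta$mark, time_point = paste0("T", meta$time),
                     brain_region = "cortex",
                     replicate_group = sprintf("%s_T%d", meta$mark,
                                               meta$time),
                     row.names = colnames(counts))
    ec <- EnhancerCounts(counts, rowRanges = granges(regions),
                         sampleData = sd)
    list(counts = ec, truth = list(differential = diffFlag, lfc = lfc))
}

#' Simulate the gene-linking layer (genes, TADs, loops, expression)
#'
#' TADs tile each chromosome at `tadSize`; genes get TSS positions spread
#' over the chromosome; loops connect the 10 kb bin holding an enhancer
#' midpoint to the bin holding a gene TSS, choosing an intra-TAD partner
#' with probability `intraTadFrac`. Genes linked to differential enhancers
#' get higher simulated fetal FPKM.
#'
#' @param config a [simulationConfig()].
#' @param enhancers GRanges of enhancers/pCRs to link.
#' @param differential logical vector flagging differential enhancers.
#' @return list with `genes` (data.frame), `tads` (GRanges + `context`),
#'   `loops` ([S4Vectors::Pairs] + `context`, `significant`), `expression`
#'   (FPKM matrix genes x samples) and `truth` (`linkedGene` per enhancer,
#'   `NA` when unlinked).
#' @export
simulateLinkingLayer <- function(config, enhancers, differential = NULL) {
    set.seed(.streamSeed(config$seed, "linking"))
    chrom <- names(config$genome)[1L]
    chrLen <- config$genome[[1L]]
    if (is.null(differential)) differential <- rep(FALSE, length(enhancers))
    res <- config$loopResolution
    tadStarts <- seq(0L, chrLen - 1L, by = config$tadSize)
    tads0 <- gi(chrom, tadStarts, pmin(tadStarts + config$tadSize, chrLen))
    tads <- c(tads0, tads0)
    mcols(tads)$context <- rep(c("CP", "GZ"), each = length(tads0))
    nG <- config$nGenes
    tssPos <- sort(sample.int(chrLen - 1L, nG))
    ## keep TSSs on bin-interior positions away from enhancers' own bins
    genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(nG)),
                        chrom = chrom, tss = tssPos,
                        strand = sample(c("+", "-"), nG, replace = TRUE),
                        biotype = sample(c("protein_coding", "lincRNA",
                                           "pseudogene"), nG,
                                         replace = TRUE,
                                         prob = c(0.8, 0.1, 0.1)))
    geneTad <- findInterval(tssPos, tadStarts)
    mids <- bedStart(enhancers) + width(enhancers) %/% 2L
    enhTad <- findInterval(mids, tadStarts)
    linked <- rep(NA_character_, length(enhancers))
    loopRows <- list()
    for (i in seq_along(enhancers)) {
        if (stats::runif(1) > 0.7) next
        intra <- stats::runif(1) < config$intraTadFrac
        cand <- if (intra) which(geneTad == enhTad[i] &
                                 genes$biotype != "pseudogene")
                else which(geneTad != enhTad[i])
        if (!length(cand)) next
        g <- cand[sample.int(length(cand), 1L)]
        binE <- (mids[i] %/% res) * res
        binG <- (tssPos[g] %/% res) * res
        if (binE == binG) next
        loopRows[[length(loopRows) + 1L]] <- data.frame(
            s1 = binE, s2 = binG, context = sample(c("CP", "GZ"), 1L))
        if (intra && genes$biotype[g] == "protein_coding")
            linked[i] <- genes$gene_id[g]
    }
    loops <- if (length(loopRows)) {
        lr <- do.call(rbind, loopRows)
        p <- Pairs(gi(chrom, lr$s1, lr$s1 + res),
                   gi(chrom, lr$s2, lr$s2 + res))
        mcols(p)$context <- lr$context
        mcols(p)$significant <- TRUE
        p
    } else Pairs(GRanges(), GRanges())
    ## expression: fetal samples upweighted for genes linked to
    ## differential enhancers
    samples <- c("fetal_1", "fetal_2", "fetal_3", "adult_1", "adult_2")
    fpkm <- matrix(exp(stats::rnorm(nG * length(samples), log(5), 0.6)),
                   nG, dimnames = list(genes$gene_id, samples))
    up <- genes$gene_id %in% linked[differential]
    fpkm[up, 1:3] <- fpkm[up, 1:3] * 2.5
    list(genes = genes, tads = tads, loops = loops, expression = fpkm,
         truth = list(linkedGene = linked))
}

#' Simulate score tracks, repeat annotations, and variant sets
#'
#' The score track is a flat background with a Gaussian bump (sd = length/6)
#' centred on every region, sampled at 10 bp resolution — mirroring the
#' elevated central signal the bin metaprofiles are designed to detect.
#' Repeats of one family are planted with a configurable O/E enrichment in
#' the differential set; case/control variants (1 bp) hit differential
#' regions with probabilities implied by the target odds ratio.
#'
#' @param config a [simulationConfig()].
#' @param regions GRanges of regions (the pCR universe).
#' @param differential logical flags (the DAE truth).
#' @param enrichedFamily,enrichFactor repeat family planted with the given
#'   O/E ratio in the differential set (default "AluY" at 2).
#' @return list with `track` (scored GRanges), `repeats` (GRanges +
#'   `family`), `caseVariants`, `controlVariants` (GRanges) and `truth`
#'   (planted OR and repeat enrichment).
#' @export
simulateTracksRepeatsVariants <- function(config, regions, differential,
                                          enrichedFamily = "AluY",
                                          enrichFactor = 2) {
    set.seed(.streamSeed(config$seed, "tracks"))
    chrom <- as.character(seqnames(regions))[1L]
    ## --- score track ---
    pieces <- lapply(seq_along(regions), function(i) {
        s <- bedStart(regions[i]); e <- bedEnd(regions[i])
        xs <- seq(s, e - 1L, by = 10L)
        ctr <- (s + e) / 2
        val <- config$trackBaseline +
            config$bumpAmplitude * exp(-((xs + 5 - ctr)^2) /
                                       (2 * ((e - s) / 6)^2)) +
            stats::rnorm(length(xs), 0, 0.01)
        data.frame(start = xs, end = pmin(xs + 10L, e), val = val)
    })
    td <- do.call(rbind, pieces)
    track <- gi(chrom, td$start, td$end, score = round(td$val, 5))
    ## --- repeats ---
    set.seed(.streamSeed(config$seed, "repeats"))
    w <- mean(differential)
    pBase <- 0.25
    pDiff <- if (w < 1 && enrichFactor * w < 1)
        enrichFactor * (1 - w) * pBase / (1 - enrichFactor * w)
    else pBase
    pDiff <- min(pDiff, 1)
    famProb <- ifelse(differential, pDiff, pBase)
    hit <- stats::runif(length(regions)) < famProb
    mkRepeat <- function(idx, family) {
        if (!length(idx)) return(NULL)
        s <- bedStart(regions[idx]) +
            round(stats::runif(length(idx)) *
                  pmax(width(regions[idx]) - 30L, 1L))
        data.frame(start = s, end = s + 30L, family = family)
    }
    neutral <- stats::runif(length(regions)) < 0.3
    rd <- rbind(mkRepeat(which(hit), enrichedFamily),
                mkRepeat(which(neutral), "L1M"),
                mkRepeat(which(stats::runif(length(regions)) < 0.005),
                         "rareTE"))
    reps <- gi(chrom, rd$start, rd$end, family = rd$family)
    ## --- variants ---
    vr <- simulateVariantSets(config, regions, differential)
    list(track = track, repeats = reps, caseVariants = vr$caseVariants,
         controlVariants = vr$controlVariants,
         truth = c(vr$truth,
                   list(enrichedFamily = enrichedFamily,
                        enrichFactor = enrichFactor)))
}

#' Simulate case/control variant sets with a target odds ratio
#'
#' Control variants overlap a differential region with probability
#' `baselineHitRate`; case variants with the probability whose odds are
#' `targetOR` times the control odds, so the expected case/control 2x2
#' overlap table has the configured odds ratio. Non-hitting variants land
#' in inter-region gaps, never overlapping any region.
#'
#' @param config a [simulationConfig()].
#' @param regions GRanges of the region universe.
#' @param differential logical flags of the differential subset.
#' @return list with `caseVariants`, `controlVariants` (1 bp GRanges) and
#'   `truth` (target OR and hit probabilities).
#' @export
simulateVariantSets <- function(config, regions, differential) {
    set.seed(.streamSeed(config$seed, "variants"))
    chrom <- as.character(seqnames(regions))[1L]
    p0 <- config$baselineHitRate
    odds1 <- config$targetOR * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    if (p1 >= 1) stop("unattainable odds ratio for given baseline rate")
    daeIdx <- which(differential)
    if (!length(daeIdx)) stop("no differential regions to place variants in")
    placeVariants <- function(nVar, pHit) {
        inDae <- stats::runif(nVar) < pHit
        pos <- integer(nVar)
        ri <- sample(daeIdx, nVar, replace = TRUE)
        pos[inDae] <- bedStart(regions[ri[inDae]]) +
            (seq_len(sum(inDae)) %% pmax(width(regions[ri[inDae]]), 1L))
        ## background positions: in the guaranteed gap just before (or just
        ## after) a region, never overlapping any region
        bi <- sample(seq_along(regions), sum(!inDae), replace = TRUE)
        st <- bedStart(regions[bi]); en <- bedEnd(regions[bi])
        pos[!inDae] <- ifelse(st >= 100L, st - 100L, en + 450L)
        gi(chrom, pos, pos + 1L)
    }
    list(caseVariants = placeVariants(config$nCaseVariants, p1),
         controlVariants = placeVariants(config$nControlVariants, p0),
         truth = list(targetOR = config$targetOR, pCase = p1,
                      pControl = p0))
}

#' Simulate every pipeline input and write it to disk
#'
#' Writes `enhancers.bed`, `counts.tsv`, `meta.tsv`, `genes.tsv`,
#' `loops.bedpe`, `tads.bed`, `tracks/score.bedGraph`, `repeats.bed`,
#' `variants_case.bed`, `variants_control.bed` and `truth.json` under
#' `outdir`. Identical config and seed produce byte-identical files.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the list of generated in-memory objects.
#' @export
simulateAll <- function(config, outdir) {
    dir.create(file.path(outdir, "tracks"), recursive = TRUE,
               showWarnings = FALSE)
    src <- simulateEnhancerSources(config)
    pcrs <- derivePCRs(deduplicateEnhancers(src$enhancers))
    cnt <- simulateEpigenomeCounts(config, pcrs)
    lnk <- simulateLinkingLayer(config, pcrs, cnt$truth$differential)
    trk <- simulateTracksRepeatsVariants(config, pcrs,
                                         cnt$truth$differential)
    enh <- src$enhancers
    mcols(enh)$name <- enh$source
    mcols(enh) <- mcols(enh)[, "name", drop = FALSE]
    writeBed(enh, file.path(outdir, "enhancers.bed"))
    writeCountMatrix(countsMatrix(cnt$counts), file.path(outdir,
                                                         "counts.tsv"),
                     idColumn = "pcr_id")
    meta <- as.data.frame(colData(cnt$counts))
    meta <- data.frame(sample_id = rownames(meta), meta, row.names = NULL)
    writeTsv(meta, file.path(outdir, "meta.tsv"))
    writeTsv(lnk$genes, file.path(outdir, "genes.tsv"))
    loops <- lnk$loops
    mcols(loops)$name <- mcols(loops)$context
    mcols(loops)$score <- 1L
    writeBedpe(loops, file.path(outdir, "loops.bedpe"))
    tadsOut <- lnk$tads
    mcols(tadsOut)$name <- tadsOut$context
    mcols(tadsOut) <- mcols(tadsOut)[, "name", drop = FALSE]
    writeBed(tadsOut, file.path(outdir, "tads.bed"))
    writeBedGraph(trk$track, file.path(outdir, "tracks", "score.bedGraph"))
    repsOut <- trk$repeats
    mcols(repsOut)$name <- repsOut$family
    mcols(repsOut) <- mcols(repsOut)[, "name", drop = FALSE]
    writeBed(repsOut, file.path(outdir, "repeats.bed"))
    writeBed(trk$caseVariants, file.path(outdir, "variants_case.bed"))
    writeBed(trk$controlVariants, file.path(outdir, "variants_control.bed"))
    writeTsv(data.frame(gene_id = rownames(lnk$expression),
                        lnk$expression, check.names = FALSE),
             file.path(outdir, "expression.tsv"))
    truth <- list(seed = config$seed,
                  n_true_enhancers = length(src$truth$trueEnhancers),
                  differential = cnt$truth$differential,
                  lfc = cnt$truth$lfc,
                  linked_gene = lnk$truth$linkedGene,
                  target_or = trk$truth$targetOR)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(sources = src, pcrs = pcrs, counts = cnt, linking = lnk,
                   tracks = trk))
}
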