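## End-to-end orchestration: derive pCRs -> call DAEs -> link genes ->
## profile features -> enrichment -> temporal clustering, with plain-text
## intermediates and a reproducible run manifest.

.stageManifest <- function(stage, params, outputs, rows, t0) {
    list(stage = stage, parameters = params,
         outputs = as.list(outputs),
         output_md5 = as.list(tools::md5sum(unlist(outputs))),
         rows = rows,
         wall_time_s = round(as.numeric(Sys.time()) - t0, 3))
}

#' Run the integrative enhancer pipeline end to end
#'
#' Reads the inputs written by [simulateAll()] (or real inputs in the same
#' formats) from `inputDir`, executes every stage in order, persists
#' plain-text intermediates under `outdir`, and returns a manifest of
#' parameters, output paths, md5 hashes and row counts per stage. A stage
#' failure aborts with the failing stage named; the partial manifest is
#' written to `manifest.json` regardless.
#'
#' @param inputDir directory with `enhancers.bed`, `counts.tsv`,
#'   `meta.tsv`, `genes.tsv`, `loops.bedpe`, `tads.bed`,
#'   `tracks/score.bedGraph`, `repeats.bed`, `variants_case.bed`,
#'   `variants_control.bed`.
#' @param outdir output directory.
#' @param alpha,minAnalyses,priorDf differential-activity parameters.
#' @param minLen,maxLen,tssUp,tssDown,minReads,minSamples pCR filters.
#' @param clusterK number of temporal clusters, or `"auto"` for bootstrap
#'   selection.
#' @param seed RNG seed (clustering bootstrap).
#' @return the run manifest (list), invisibly written as
#'   `outdir/manifest.json`.
#' @export
runPipeline <- function(inputDir, outdir, alpha = 0.05, minAnalyses = 2L,
                        priorDf = 10, minLen = 50L, maxLen = 1000L,
                        tssUp = 2000L, tssDown = 1000L, minReads = 10L,
                        minSamples = 2L, clusterK = "auto", seed = 1L) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(seed = seed, stages = list())
    finish <- function() {
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        invisible(manifest)
    }
    runStage <- function(name, fn) {
        t0 <- as.numeric(Sys.time())
        res <- tryCatch(fn(t0), error = function(e) {
            finish()
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
        manifest$stages[[name]] <<- res$manifest
        res$value
    }

    ## stage 1: derive pCRs
    pcrs <- runStage("derive_pcrs", function(t0) {
        enh <- readBed(file.path(inputDir, "enhancers.bed"))
        mcols(enh)$source <- enh$name
        genes <- readTsv(file.path(inputDir, "genes.tsv"))
        counts <- readCountMatrix(file.path(inputDir, "counts.tsv"))
        p <- derivePCRs(deduplicateEnhancers(enh), minLen, maxLen)
        p <- excludeTssProximal(p, genes, tssUp, tssDown)
        p <- filterMinCoverage(p[p$id %in% rownames(counts)],
                               counts, minReads, minSamples)
        out <- file.path(outdir, "pcrs.bed")
        pb <- granges(p); mcols(pb)$name <- p$id
        mcols(pb)$score <- p$n_sources
        writeBed(pb, out)
        list(value = p, manifest = .stageManifest(
            "derive_pcrs",
            list(minLen = minLen, maxLen = maxLen, tssUp = tssUp,
                 tssDown = tssDown, minReads = minReads,
                 minSamples = minSamples),
            out, length(p), t0))
    })

    ## stage 2: differential activity
    da <- runStage("call_daes", function(t0) {
        counts <- readCountMatrix(file.path(inputDir, "counts.tsv"))
        meta <- readTsv(file.path(inputDir, "meta.tsv"))
        rownames(meta) <- meta$sample_id
        counts <- counts[rownames(counts) %in% pcrs$id, , drop = FALSE]
        ec <- EnhancerCounts(counts, rowRanges = NULL,
                             sampleData = meta[colnames(counts), ])
        ec <- groupReplicates(ec)
        d <- runDifferentialActivity(ec, alpha = alpha,
                                     minAnalyses = minAnalyses,
                                     priorDf = priorDf)
        out <- file.path(outdir, "dae_labels.tsv")
        writeTsv(as.data.frame(daeLabels(d)), out)
        out2 <- file.path(outdir, "dae_calls.tsv")
        writeTsv(as.data.frame(daeCalls(d)), out2)
        list(value = d, manifest = .stageManifest(
            "call_daes", list(alpha = alpha, minAnalyses = minAnalyses,
                              priorDf = priorDf),
            c(out, out2), nrow(daeLabels(d)), t0))
    })
    labels <- daeLabels(da)
    daeSet <- pcrs[pcrs$id %in% labels$pcr_id[labels$label == "DAE"]]
    ndaeSet <- pcrs[pcrs$id %in% labels$pcr_id[labels$label == "nDAE"]]

    ## stage 3: gene linking
    links <- runStage("link_genes", function(t0) {
        loops <- readBedpe(file.path(inputDir, "loops.bedpe"))
        tads <- readBed(file.path(inputDir, "tads.bed"))
        genes <- readTsv(file.path(inputDir, "genes.tsv"))
        l <- linkEnhancersToGenes(pcrs, loops, tads, genes)
        out <- file.path(outdir, "links.tsv")
        writeTsv(as.data.frame(l), out)
        list(value = l, manifest = .stageManifest(
            "link_genes", list(resolution = 10000L), out, nrow(l), t0))
    })

    ## stage 4: feature metaprofile
    runStage("profile", function(t0) {
        track <- readBedGraph(file.path(inputDir, "tracks",
                                        "score.bedGraph"))
        prof <- profileRegions(
            if (length(daeSet)) daeSet else pcrs, track, stat = "median")
        out <- file.path(outdir, "profile.tsv")
        writeTsv(prof, out)
        list(value = prof, manifest = .stageManifest(
            "profile", list(binSize = 10L, stat = "median"), out,
            nrow(prof), t0))
    })

    ## stage 5: enrichment
    runStage("enrich", function(t0) {
        reps <- readBed(file.path(inputDir, "repeats.bed"))
        mcols(reps)$family <- reps$name
        te <- teEnrichment(pcrs, list(DAE = daeSet, nDAE = ndaeSet), reps)
        caseV <- readBed(file.path(inputDir, "variants_case.bed"))
        ctrlV <- readBed(file.path(inputDir, "variants_control.bed"))
        aHit <- sum(overlapsAny(caseV, daeSet, ignore.strand = TRUE))
        bHit <- sum(overlapsAny(ctrlV, daeSet, ignore.strand = TRUE))
        cr <- oddsRatio(matrix(c(aHit, length(caseV) - aHit,
                                 bHit, length(ctrlV) - bHit), 2L,
                               byrow = TRUE))
        out <- file.path(outdir, "te_enrichment.tsv")
        writeTsv(te, out)
        out2 <- file.path(outdir, "variant_enrichment.tsv")
        writeTsv(data.frame(a = aHit, b = length(caseV) - aHit,
                            c = bHit, d = length(ctrlV) - bHit,
                            odds_ratio = oddsRatioValue(cr),
                            p = fisherPValue(cr),
                            ci_low = confInt(cr)[1],
                            ci_high = confInt(cr)[2]), out2)
        list(value = list(te = te, variants = cr),
             manifest = .stageManifest(
                 "enrich", list(minOverlap = 15L), c(out, out2),
                 nrow(te), t0))
    })

    ## stage 6: temporal clustering of DAEs
    runStage("cluster", function(t0) {
        counts <- readCountMatrix(file.path(inputDir, "counts.tsv"))
        dm <- counts[rownames(counts) %in% daeSet$id, , drop = FALSE]
        if (nrow(dm) < 10L)
            return(list(value = NULL, manifest = .stageManifest(
                "cluster", list(skippedFewDAEs = TRUE), character(), 0L,
                t0)))
        f <- tmmFactors(dm)
        logn <- log2(t(t(dm) / (colSums(dm) * f)) * 1e6 + 0.5)
        dmat <- spearmanDistance(logn)
        k <- if (identical(clusterK, "auto"))
            selectK(dmat, nBoot = 50L, seed = seed) else as.integer(clusterK)
        cl <- pamCluster(dmat, k)
        out <- file.path(outdir, "clusters.tsv")
        writeTsv(data.frame(pcr_id = rownames(dm),
                            cluster = cl$assignment,
                            silhouette = cl$silhouette), out)
        list(value = cl, manifest = .stageManifest(
            "cluster", list(k = k), out, nrow(dm), t0))
    })

    manifest$counts <- list(pcrs = length(pcrs),
                            dae = sum(labels$label == "DAE"),
                            ndae = sum(labels$label == "nDAE"),
                            links = nrow(links))
    finish()
}
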