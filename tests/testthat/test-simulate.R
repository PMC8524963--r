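test_that("enhancer source simulation is deterministic and recoverable", {
    cfg <- simulationConfig(seed = 101, nTrueEnhancers = 120,
                            genome = c(chr1 = 4000000L))
    a <- simulateEnhancerSources(cfg)
    b <- simulateEnhancerSources(cfg)
    expect_identical(a$enhancers, b$enhancers)

    # zero jitter: every source reports identical coordinates, so derived
    # pCRs coincide with multi-source true enhancers
    cfg0 <- simulationConfig(seed = 102, nTrueEnhancers = 80,
                             genome = c(chr1 = 4000000L), jitterSd = 0)
    s0 <- simulateEnhancerSources(cfg0)
    p0 <- derivePCRs(deduplicateEnhancers(s0$enhancers))
    multi <- s0$truth$trueEnhancers[s0$truth$nSourcesPerEnhancer >= 1]
    hit <- overlapsAny(multi, p0)
    expect_gte(mean(hit), 0.95)
    exact <- countOverlaps(p0, s0$truth$trueEnhancers, type = "equal")
    expect_gte(mean(exact > 0), 0.9)

    # with jitter, >= 90% of multi-source true enhancers are recovered
    cfgJ <- simulationConfig(seed = 103, nTrueEnhancers = 150,
                             genome = c(chr1 = 5000000L), jitterSd = 20)
    sj <- simulateEnhancerSources(cfgJ)
    pj <- derivePCRs(deduplicateEnhancers(sj$enhancers))
    multiJ <- sj$truth$trueEnhancers[sj$truth$nSourcesPerEnhancer >= 2]
    expect_gte(mean(overlapsAny(multiJ, pj)), 0.9)

    expect_error(simulateEnhancerSources(
        simulationConfig(seed = 1, nTrueEnhancers = 1e5,
                         genome = c(chr1 = 100000L))), "too small")
})

test_that("count simulation matches its declared NB model", {
    cfg <- simulationConfig(seed = 104, dispersion = 0)
    regions <- gi("chr1", seq(0, by = 1000, length.out = 3000),
                  seq(0, by = 1000, length.out = 3000) + 500)
    cnt <- simulateEpigenomeCounts(cfg, regions)
    m <- countsMatrix(cnt$counts)
    # Poisson limit: per-column variance/mean of null regions close to 1
    nullR <- !cnt$truth$differential
    disp <- apply(m[nullR, ], 2, function(x) var(x) / mean(x))
    # overdispersion across regions comes from rel_g spread; compare to the
    # same statistic under NB dispersion 0.05, which must be clearly larger
    cfg2 <- simulationConfig(seed = 104, dispersion = 0.05)
    m2 <- countsMatrix(simulateEpigenomeCounts(cfg2, regions)$counts)
    disp2 <- apply(m2[nullR, ], 2, function(x) var(x) / mean(x))
    expect_true(all(disp2 > disp))

    # planted fold changes: last vs first time point ratio tracks 2^(2*lfc)
    cfg3 <- simulationConfig(seed = 105)
    cnt3 <- simulateEpigenomeCounts(cfg3, regions)
    m3 <- countsMatrix(cnt3$counts)
    dif <- cnt3$truth$differential
    up <- dif & cnt3$truth$lfc > 0
    t1 <- rowMeans(m3[, grepl("H3K27ac_T1", colnames(m3))])
    t3 <- rowMeans(m3[, grepl("H3K27ac_T3", colnames(m3))])
    ratioUp <- median(log2((t3[up] + 0.5) / (t1[up] + 0.5)))
    ratioNull <- median(log2((t3[!dif] + 0.5) / (t1[!dif] + 0.5)))
    expect_gt(ratioUp - ratioNull, 1.8)  # 2 transitions at lfc >= 1
    expect_equal(mean(dif), 0.1, tolerance = 0.15)
})

test_that("linking layer geometry honours the intra-TAD fraction", {
    cfg <- simulationConfig(seed = 106, nTrueEnhancers = 150,
                            genome = c(chr1 = 5000000L), intraTadFrac = 1)
    src <- simulateEnhancerSources(cfg)
    pcrs <- derivePCRs(deduplicateEnhancers(src$enhancers))
    lnk <- simulateLinkingLayer(cfg, pcrs, rep(FALSE, length(pcrs)))
    loops <- lnk$loops
    tadIdx <- function(pos) findInterval(pos, seq(0, 5000000, 400000))
    sameTad <- tadIdx(bedStart(first(loops))) ==
        tadIdx(bedStart(second(loops)))
    expect_true(all(sameTad))

    # same seed -> identical loops
    lnk2 <- simulateLinkingLayer(cfg, pcrs, rep(FALSE, length(pcrs)))
    expect_identical(as.data.frame(first(lnk2$loops)),
                     as.data.frame(first(loops)))

    # genes linked to differential enhancers express higher in fetal samples
    cfgE <- simulationConfig(seed = 107, nTrueEnhancers = 200,
                             genome = c(chr1 = 7000000L))
    srcE <- simulateEnhancerSources(cfgE)
    pE <- derivePCRs(deduplicateEnhancers(srcE$enhancers))
    diffE <- seq_along(pE) %% 2 == 0
    lnkE <- simulateLinkingLayer(cfgE, pE, diffE)
    linked <- unique(na.omit(lnkE$truth$linkedGene[diffE]))
    other <- setdiff(rownames(lnkE$expression), linked)
    fetal <- rowMeans(lnkE$expression[, 1:3])
    expect_lt(rankSumTest(fetal[linked], fetal[other]), 0.01)
    expect_gt(median(fetal[linked]), median(fetal[other]))
})

test_that("variant generator hits the target odds ratio in expectation", {
    cfg <- simulationConfig(seed = 108, nTrueEnhancers = 300,
                            genome = c(chr1 = 10000000L))
    regions <- gi("chr1", seq(0, by = 3000, length.out = 2000),
                  seq(0, by = 3000, length.out = 2000) + 600)
    dif <- seq_along(regions) <= 400
    trk <- simulateTracksRepeatsVariants(cfg, regions, dif)
    daeSet <- regions[dif]
    a <- sum(overlapsAny(trk$caseVariants, daeSet))
    b <- sum(overlapsAny(trk$controlVariants, daeSet))
    or <- oddsRatioValue(oddsRatio(c(
        a, length(trk$caseVariants) - a,
        b, length(trk$controlVariants) - b)))
    expect_gt(or, 1.5); expect_lt(or, 2.7)
    # control variants never fall inside regions other than planted hits
    expect_equal(sum(overlapsAny(trk$controlVariants, regions)), b)

    # planted repeat family enrichment recovered by the TE statistic
    te <- teEnrichment(regions, list(DAE = daeSet), trk$repeats)
    alu <- te[te$family == trk$truth$enrichedFamily, ]
    expect_gt(alu$OE, 1.6); expect_lt(alu$OE, 2.4)
})

test_that("simulateAll writes a byte-stable, reader-valid input bundle", {
    cfg <- simulationConfig(seed = 109, nTrueEnhancers = 60,
                            genome = c(chr1 = 2000000L), nGenes = 40)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateAll(cfg, d1)
    simulateAll(cfg, d2)
    files <- list.files(d1, recursive = TRUE)
    expect_true(all(c("enhancers.bed", "counts.tsv", "meta.tsv",
                      "genes.tsv", "loops.bedpe", "tads.bed",
                      "tracks/score.bedGraph", "repeats.bed",
                      "variants_case.bed", "variants_control.bed",
                      "truth.json") %in% files))
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
    # every emitted file loads through its module reader
    expect_s4_class(readBed(file.path(d1, "enhancers.bed")), "GRanges")
    expect_true(is.matrix(readCountMatrix(file.path(d1, "counts.tsv"))))
    expect_s4_class(readBedpe(file.path(d1, "loops.bedpe")), "Pairs")
    expect_s4_class(readBedGraph(file.path(d1, "tracks/score.bedGraph")),
                    "GRanges")
    expect_s4_class(readBed(file.path(d1, "tads.bed")), "GRanges")
})
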