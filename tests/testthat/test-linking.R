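makeLinkFixture <- function() {
    # one chromosome, two TADs per context: [0, 100kb) and [100kb, 200kb)
    tads <- gi("chr1", c(0, 100000, 0, 100000),
               c(100000, 200000, 100000, 200000),
               context = c("CP", "CP", "GZ", "GZ"))
    pcrs <- gi("chr1", c(15000, 115000), c(15400, 115400),
               id = c("pcr1", "pcr2"))
    genes <- data.frame(
        gene_id = c("gPC", "gLinc", "gPseudo", "gFar"),
        chrom = "chr1",
        tss = c(42000, 45000, 41000, 142000),
        strand = c("+", "-", "+", "+"),
        biotype = c("protein_coding", "lincRNA", "pseudogene",
                    "protein_coding"))
    list(tads = tads, pcrs = pcrs, genes = genes)
}

mkLoops <- function(s1, s2, context = "CP", significant = TRUE) {
    p <- Pairs(gi("chr1", s1, s1 + 10000), gi("chr1", s2, s2 + 10000))
    mcols(p)$context <- context
    mcols(p)$significant <- significant
    p
}

test_that("links require anchor hits, same TAD, same context, allowed biotype", {
    fx <- makeLinkFixture()
    # pcr1 (bin 10k-20k) to gPC TSS (bin 40k-50k), intra-TAD
    # gPC (protein-coding) and gLinc (lincRNA) share the partner bin and
    # both qualify; the pseudogene in the same bin never does
    l <- linkEnhancersToGenes(fx$pcrs, mkLoops(10000, 40000), fx$tads,
                              fx$genes)
    expect_equal(nrow(l), 2L)
    expect_equal(unique(l$pcr_id), "pcr1")
    expect_setequal(l$gene_id, c("gPC", "gLinc"))
    expect_equal(unique(l$context), "CP")

    # anchors swapped still links (pair membership is symmetric)
    l2 <- linkEnhancersToGenes(fx$pcrs, mkLoops(40000, 10000), fx$tads,
                               fx$genes)
    expect_setequal(l2$gene_id, c("gPC", "gLinc"))

    # cross-TAD partner: pcr1 to gFar (other TAD) -> no link
    l3 <- linkEnhancersToGenes(fx$pcrs, mkLoops(10000, 140000), fx$tads,
                               fx$genes)
    expect_equal(nrow(l3), 0L)

    # pseudogene in the same anchor bin as gPC/gLinc is never linked
    l4 <- linkEnhancersToGenes(fx$pcrs, mkLoops(10000, 40000), fx$tads,
                               fx$genes)
    expect_false("gPseudo" %in% l4$gene_id)

    # non-significant interactions are ignored
    l5 <- linkEnhancersToGenes(fx$pcrs,
                               mkLoops(10000, 40000, significant = FALSE),
                               fx$tads, fx$genes)
    expect_equal(nrow(l5), 0L)

    # wrong resolution warns
    p <- Pairs(gi("chr1", 10000, 15000), gi("chr1", 40000, 45000))
    mcols(p)$context <- "CP"; mcols(p)$significant <- TRUE
    expect_warning(linkEnhancersToGenes(fx$pcrs, p, fx$tads, fx$genes),
                   "resolution")
})

test_that("emitted links verify by independent per-base containment", {
    fx <- makeLinkFixture()
    set.seed(51)
    loops <- mkLoops(c(sample(seq(0, 190000, 10000), 30, TRUE), 10000),
                     c(sample(seq(0, 190000, 10000), 30, TRUE), 40000),
                     context = c(sample(c("CP", "GZ"), 30, TRUE), "GZ"))
    l <- linkEnhancersToGenes(fx$pcrs, loops, fx$tads, fx$genes)
    expect_gt(nrow(l), 0L)
    if (nrow(l)) for (i in seq_len(nrow(l))) {
        pc <- fx$pcrs[fx$pcrs$id == l$pcr_id[i]]
        gn <- fx$genes[fx$genes$gene_id == l$gene_id[i], ]
        midBase <- bedStart(pc) + width(pc) %/% 2
        hitPair <- FALSE
        for (j in seq_along(loops)) {
            if (mcols(loops)$context[j] != l$context[i]) next
            a1 <- c(bedStart(first(loops))[j], bedEnd(first(loops))[j])
            a2 <- c(bedStart(second(loops))[j], bedEnd(second(loops))[j])
            pcHit1 <- bedStart(pc) < a1[2] && bedEnd(pc) > a1[1]
            pcHit2 <- bedStart(pc) < a2[2] && bedEnd(pc) > a2[1]
            gHit1 <- gn$tss >= a1[1] && gn$tss < a1[2]
            gHit2 <- gn$tss >= a2[1] && gn$tss < a2[2]
            if ((pcHit1 && gHit2) || (pcHit2 && gHit1)) hitPair <- TRUE
        }
        expect_true(hitPair)
        sameTad <- (midBase < 100000) == (gn$tss < 100000)
        expect_true(sameTad)
        expect_true(gn$biotype %in% c("protein_coding", "lincRNA"))
    }
})

test_that("link tallies bucket at 5+ and are order-invariant", {
    links <- S4Vectors::DataFrame(
        pcr_id = c(rep("p1", 6), "p2", "p2", "p3"),
        gene_id = c(paste0("g", 1:6), "g1", "g2", "g1"),
        biotype = "protein_coding", context = "CP", tad_id = "t1")
    lc <- linkCounts(links)
    expect_equal(lc$perEnhancer$bucket[lc$perEnhancer$id == "p1"], "5+")
    expect_equal(lc$perEnhancer$n[lc$perEnhancer$id == "p2"], 2L)
    expect_equal(lc$perGene$n[lc$perGene$id == "g1"], 3L)
    shuffled <- links[sample(nrow(links)), ]
    lc2 <- linkCounts(shuffled)
    expect_equal(lc2$perEnhancer[order(lc2$perEnhancer$id), ],
                 lc$perEnhancer[order(lc$perEnhancer$id), ],
                 ignore_attr = TRUE)
    empty <- linkCounts(links[0, ])
    expect_equal(nrow(empty$perGene), 0L)
})

test_that("rank-sum test: exact branch equals enumeration; edge cases", {
    expect_equal(rankSumTest(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
    expect_equal(rankSumTest(c(5, 5, 5), c(5, 5)), 1)

    set.seed(52)
    for (rep in 1:20) {
        nx <- sample(2:8, 1); ny <- sample(2:8, 1)
        vals <- sample(1000, nx + ny)  # tie-free
        x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
        expect_equal(rankSumTest(x, y), oracleRankSum(x, y),
                     tolerance = 1e-12, info = paste("rep", rep))
    }

    # large-sample branch with ties stays close to a permutation oracle
    set.seed(53)
    x <- sample(1:8, 30, replace = TRUE)
    y <- sample(3:10, 30, replace = TRUE)
    got <- rankSumTest(x, y)
    pooled <- c(x, y); nx <- length(x)
    r <- rank(pooled)
    wObs <- sum(r[seq_len(nx)])
    perm <- replicate(20000, {
        idx <- sample(length(pooled), nx)
        sum(r[idx])
    })
    pPerm <- mean(abs(perm - mean(perm)) >= abs(wObs - mean(perm)) - 1e-9)
    expect_lt(abs(got - pPerm), 0.02)
})

test_that("trajectory odds ratios recover construction and flag gaps", {
    set.seed(54)
    traj <- c(rep("falling", 300), rep("rising", 300), rep("constant", 400))
    names(traj) <- paste0("g", 1:1000)
    # DAE genes enriched for falling
    dae <- c(sample(names(traj)[traj == "falling"], 150),
             sample(names(traj)[traj != "falling"], 150))
    ndae <- sample(names(traj), 400)
    res <- trajectoryOdds(dae, ndae, traj)
    expect_setequal(res$trajectory, c("falling", "rising", "constant"))
    orF <- res$odds_ratio[res$trajectory == "falling"]
    expect_gt(orF, 1)

    # identical proportions -> OR 1
    same <- trajectoryOdds(names(traj)[1:100], names(traj)[1:100], traj)
    expect_true(all(abs(same$odds_ratio - 1) < 1e-12))

    expect_error(trajectoryOdds(c("gX"), dae, traj), "gX")
    expect_error(trajectoryOdds(character(), ndae, traj), "non-empty")
})
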