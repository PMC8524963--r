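test_that("countReads uses >= 1 base overlap, half-open", {
    pcrs <- gi("chr1", c(200, 600), c(300, 700), id = c("p1", "p2"))
    reads <- list(s1 = gi("chr1", c(150, 100), c(250, 200)),
                  s2 = gi("chr1", 290, 650))
    ec <- countReads(pcrs, reads)
    m <- countsMatrix(ec)
    expect_equal(m["p1", ], c(s1 = 1L, s2 = 1L))  # abutting read not counted
    expect_equal(m["p2", ], c(s1 = 0L, s2 = 1L))

    set.seed(31)
    df <- randomIntervals(300, 20000, minW = 30, maxW = 100)
    rd <- gi("chr1", df$start, df$end)
    pc <- gi("chr1", seq(0, 19000, by = 1000), seq(0, 19000, by = 1000) + 500,
             id = sprintf("r%02d", 1:20))
    got <- countsMatrix(countReads(pc, list(s = rd)))[, 1]
    brute <- vapply(seq_along(pc), function(i)
        sum(pmin(bedEnd(pc)[i], df$end) - pmax(bedStart(pc)[i], df$start) >= 1),
        numeric(1))
    expect_equal(unname(got), as.integer(brute))
})

test_that("TMM factors: identity, pure depth scaling, scale invariance", {
    set.seed(32)
    base <- matrix(rnbinom(400 * 4, mu = 60, size = 10), 400, 4)
    same <- cbind(base[, 1], base[, 1], base[, 1])
    expect_equal(unname(tmmFactors(same)), rep(1, 3))

    depth <- cbind(base[, 1], base[, 1] * 2L)
    expect_equal(unname(tmmFactors(depth)), c(1, 1))

    # scaling one column leaves M values and trims untouched; only the
    # precision weights of that column rescale, so invariance is near-exact
    f1 <- tmmFactors(base)
    scaled <- base; scaled[, 2] <- scaled[, 2] * 5L
    expect_equal(unname(tmmFactors(scaled)), unname(f1), tolerance = 0.02)
    expect_equal(exp(mean(log(f1))), 1, tolerance = 1e-9)
})

test_that("TMM matches a hand-computed trimmed weighted mean on a toy", {
    # 20-region toy, sample 2 composition-shifted; oracle computed step by
    # step (independent of the package code path)
    set.seed(33)
    y1 <- rpois(20, 100)
    y2 <- y1; y2[1:4] <- y2[1:4] * 4L
    m <- cbind(y1, y2)
    N <- colSums(m)
    logR <- log2((m[, 2] / N[2]) / (m[, 1] / N[1]))
    absE <- 0.5 * log2((m[, 2] / N[2]) * (m[, 1] / N[1]))
    w <- (N[2] - m[, 2]) / (N[2] * m[, 2]) + (N[1] - m[, 1]) / (N[1] * m[, 1])
    n <- length(logR)
    keep <- rank(logR) >= floor(n * .3) + 1 & rank(logR) <= n - floor(n * .3) &
            rank(absE) >= floor(n * .05) + 1 & rank(absE) <= n - floor(n * .05)
    f2 <- 2^(sum(logR[keep] / w[keep]) / sum(1 / w[keep]))
    expected <- c(1 / sqrt(f2), f2 / sqrt(f2))  # geometric-mean rescaling
    got <- tmmFactors(m, reference = 1)
    expect_equal(unname(got), unname(expected), tolerance = 1e-12)
})

test_that("TMM factors agree with the edgeR reference implementation", {
    skip_if_not_installed("edgeR")
    set.seed(34)
    m <- matrix(rnbinom(2000 * 5, mu = 40, size = 5), 2000, 5)
    m[1:100, 3] <- m[1:100, 3] * 3L
    ours <- tmmFactors(m, reference = 2)
    ref <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 2)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
    # automatic reference choice also agrees
    expect_equal(unname(tmmFactors(m)),
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-10)
})

test_that("replicate grouping joins r > threshold and isolates low correlation", {
    set.seed(35)
    base <- rnbinom(3000, mu = 100, size = 2)
    noisy <- function(rho) {
        k <- round(rho * 3000)
        out <- base
        idx <- sample(3000, 3000 - k)
        out[idx] <- rnbinom(length(idx), mu = 100, size = 2)
        out
    }
    m <- cbind(a = base, b = noisy(0.97), c = rnbinom(3000, mu = 100, size = 2))
    ec <- EnhancerCounts(m, sampleData = data.frame(
        mark = "H3K27ac", time_point = "T1", brain_region = "x",
        replicate_group = c("g1", NA, NA), row.names = colnames(m)))
    out <- colData(groupReplicates(ec))$replicate_group
    expect_equal(out[2], "g1")       # r > 0.89 with group g1
    expect_false(out[3] == "g1")     # uncorrelated -> singleton group
})

test_that("NB GLM fit: mean forcing, saturation, and likelihood-oracle agreement", {
    X <- matrix(1, 2, 1)
    fit <- fitNbGlm(c(4, 6), X, offsets = c(0, 0), dispersion = 0.1)
    expect_equal(unname(fit$mu), c(5, 5), tolerance = 1e-7)

    Xs <- diag(2)
    fs <- fitNbGlm(c(4, 6), Xs, offsets = c(0, 0), dispersion = 0.1)
    expect_equal(fs$deviance, 0, tolerance = 1e-8)

    # random row vs direct numeric likelihood maximization
    set.seed(36)
    X2 <- cbind(1, c(0, 0, 1, 1, 0, 1))
    offs <- log(runif(6, 0.8, 1.2))
    y <- rnbinom(6, mu = exp(2 + 0.7 * X2[, 2] + offs), size = 10)
    ours <- fitNbGlm(y, X2, offs, dispersion = 0.1)
    nll <- function(b) -sum(dnbinom(y, size = 10,
                                    mu = exp(drop(X2 %*% b) + offs),
                                    log = TRUE))
    oracle <- optim(c(1, 0), nll, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(unname(ours$beta), oracle$par, tolerance = 1e-3)
    # and the IRLS optimum is at least as good as the oracle's
    expect_lte(nll(ours$beta), oracle$value + 1e-6)

    expect_error(fitNbGlm(1:3, cbind(1, c(1, 1, 1)), rep(0, 3), 0.1),
                 "full column rank")
})

test_that("one-way fast path agrees with per-row IRLS fits", {
    set.seed(37)
    grp <- factor(rep(1:3, each = 2))
    X <- model.matrix(~grp)
    offs <- log(runif(6, 0.5, 2) * 1000)
    Y <- matrix(rnbinom(50 * 6, mu = 80, size = 20), 50, 6)
    fast <- enhancerDynamics:::.fitNbOneWay(Y, grp, offs, 0.05)
    for (i in c(1, 17, 50)) {
        slow <- fitNbGlm(Y[i, ], X, offs, 0.05)
        expect_equal(fast$mu[i, ], unname(slow$mu), tolerance = 1e-6)
        expect_equal(fast$deviance[i], slow$deviance, tolerance = 1e-6)
    }
    expect_equal(fast$df.residual, 3)
})

test_that("common dispersion recovers simulated truth", {
    set.seed(38)
    grp <- factor(rep(1:2, each = 3))
    mu <- exp(rnorm(2000, log(80), 0.4))
    pois <- matrix(rpois(2000 * 6, mu), 2000, 6)
    expect_lt(estimateCommonDispersion(pois, grp), 0.01)

    nb <- matrix(rnbinom(2000 * 6, mu = mu, size = 10), 2000, 6)
    phi <- estimateCommonDispersion(nb, grp)
    expect_gt(phi, 0.07); expect_lt(phi, 0.13)

    one <- matrix(rpois(10 * 2, 50), 10, 2)
    expect_error(estimateCommonDispersion(one, factor(1:2)),
                 "inestimable")
})

test_that("QL F-test: null uniformity, power on a spiked region, priorDf limit", {
    set.seed(39)
    grp <- factor(rep(1:3, each = 2))
    offs <- rep(log(1e4), 6)
    mu <- exp(rnorm(5000, log(60), 0.5))
    Y <- matrix(rnbinom(5000 * 6, mu = mu, size = 20), 5000, 6)
    phi <- estimateCommonDispersion(Y, grp, offs)
    full <- enhancerDynamics:::.fitNbOneWay(Y, grp, offs, phi)
    null <- enhancerDynamics:::.fitNbOneWay(Y, factor(rep(1, 6)), offs, phi)
    ft <- qlFTest(full, null)
    ks <- suppressWarnings(ks.test(ft$p, "punif"))
    expect_lt(unname(ks$statistic), 0.03)

    # planted 4-fold change at high depth
    Ys <- Y
    Ys[1, ] <- rnbinom(6, mu = 400 * c(1, 1, 2, 2, 4, 4), size = 20)
    full2 <- enhancerDynamics:::.fitNbOneWay(Ys, grp, offs, phi)
    null2 <- enhancerDynamics:::.fitNbOneWay(Ys, factor(rep(1, 6)), offs, phi)
    ft2 <- qlFTest(full2, null2)
    expect_lt(ft2$p[1], 1e-4)

    # priorDf -> Inf: F = (dev diff / dfTest) / mean quasi-dispersion
    ftInf <- qlFTest(full, null, priorDf = 1e12)
    s2bar <- mean(full$deviance / full$df.residual)
    expect_equal(ftInf$F,
                 pmax((null$deviance - full$deviance) / 2, 0) / s2bar,
                 tolerance = 1e-4)
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_equal(bhAdjust(0.73), 0.73)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    # against the textbook formula on a random vector
    set.seed(40)
    p <- runif(100)
    o <- order(p)
    q <- rev(cummin(rev(p[o] * 100 / seq_len(100))))
    expect_equal(bhAdjust(p)[o], pmin(q, 1))
})

test_that("DAE pooling requires significance in >= minAnalyses analyses", {
    calls <- data.frame(
        pcr_id = c("p1", "p1", "p2", "p3"),
        analysis = c("H3K27ac:time", "ATAC:time", "DNase:time", "ATAC:time"),
        fdr = c(0.01, 0.04, 0.002, 0.2))
    lab <- callDaes(calls)
    expect_equal(lab$label[lab$pcr_id == "p1"], "DAE")
    expect_equal(lab$label[lab$pcr_id == "p2"], "nDAE")
    expect_equal(lab$label[lab$pcr_id == "p3"], "nDAE")
    expect_equal(lab$n_significant_analyses[lab$pcr_id == "p1"], 2L)
})

test_that("pure-null data yields DAE fraction below alpha", {
    cfg <- simulationConfig(seed = 99, fracDifferential = 0)
    regions <- gi("chr1", seq(0, by = 1500, length.out = 2000),
                  seq(0, by = 1500, length.out = 2000) + 500)
    cnt <- simulateEpigenomeCounts(cfg, regions)
    da <- runDifferentialActivity(cnt$counts)
    expect_lt(mean(daeLabels(da)$label == "DAE"), 0.05)
})
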