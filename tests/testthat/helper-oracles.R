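# Independent brute-force oracles used across the suite. They deliberately
# work base by base (or by exhaustive enumeration) and share no code with
# the implementation paths they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# per-base boolean union of 0-based half-open intervals on one chromosome
oracleUnionMask <- function(starts, ends, maxPos) {
    mask <- logical(maxPos)
    for (i in seq_along(starts))
        if (ends[i] > starts[i])
            mask[(starts[i] + 1):ends[i]] <- TRUE  # base b -> index b+1
    mask
}

# per-base depth counts
oracleDepth <- function(starts, ends, maxPos) {
    d <- integer(maxPos)
    for (i in seq_along(starts))
        d[(starts[i] + 1):ends[i]] <- d[(starts[i] + 1):ends[i]] + 1L
    d
}

# mask/depth vector -> data.frame of 0-based half-open runs of equal value
maskToRuns <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(start = starts, end = ends, value = r$values)
}

# per-base distinct-source depth for pCR oracle
oracleSourceDepth <- function(df, maxPos) {
    d <- integer(maxPos)
    for (s in unique(df$source)) {
        sub <- df[df$source == s, ]
        m <- oracleUnionMask(sub$start, sub$end, maxPos)
        d <- d + as.integer(m)
    }
    d
}

# brute-force pCR derivation on one chromosome: per-base source depth,
# per merged cluster take maximal-depth runs (depth >= 2) or the cluster
# itself (depth 1), then the length filter
oraclePcrs <- function(df, maxPos, minLen = 50, maxLen = 1000) {
    d <- oracleSourceDepth(df, maxPos)
    runs <- maskToRuns(d)
    runs <- runs[runs$value > 0, ]
    cl <- maskToRuns(d > 0)
    cl <- cl[cl$value, ]
    out <- list()
    for (i in seq_len(nrow(cl))) {
        inCl <- runs$start >= cl$start[i] & runs$end <= cl$end[i]
        mx <- max(runs$value[inCl])
        cand <- if (mx >= 2) runs[inCl & runs$value == mx, c("start", "end")]
                else data.frame(start = cl$start[i], end = cl$end[i])
        cand$n_sources <- mx
        out[[i]] <- cand
    }
    out <- do.call(rbind, out)
    out <- out[out$end - out$start >= minLen & out$end - out$start <= maxLen, ]
    out[order(out$start), ]
}

# exact two-sided Fisher p by direct pmf enumeration with choose() ratios
# (no dhyper), R's minimum-likelihood rule
oracleFisher <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    ks <- max(0, c1 - r2):min(r1, c1)
    pmf <- vapply(ks, function(k)
        choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
    pobs <- pmf[ks == a]
    min(1, sum(pmf[pmf <= pobs * (1 + 1e-7)]))
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracleRankSum <- function(x, y) {
    pooled <- c(x, y)
    n <- length(pooled); nx <- length(x)
    r <- rank(pooled)
    wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    combs <- utils::combn(n, nx)
    ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
    mu <- nx * (n - nx) / 2
    mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# exhaustive PAM: minimal total distance over all medoid subsets
oraclePamCost <- function(d, k) {
    n <- nrow(d)
    best <- Inf
    for (subset in asplit(utils::combn(n, k), 2)) {
        cost <- sum(apply(d[, subset, drop = FALSE], 1, min))
        if (cost < best) best <- cost
    }
    best
}

# random interval fixture on one chromosome
randomIntervals <- function(n, maxPos, minW = 1, maxW = 400) {
    s <- sample.int(maxPos - maxW, n, replace = TRUE) - 1L
    w <- sample(minW:maxW, n, replace = TRUE)
    data.frame(start = s, end = pmin(s + w, maxPos))
}
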