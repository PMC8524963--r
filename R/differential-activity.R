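## Differential enhancer activity: count matrix construction, TMM
## normalization, replicate grouping, common NB dispersion by Cox-Reid
## adjusted profile likelihood, NB-GLM fitting, quasi-likelihood F-tests,
## BH adjustment, and pooling into DAE/nDAE labels.

#' Count overlapping reads per pCR and sample
#'
#' A read contributes to a pCR when the two intervals share at least one
#' base (half-open arithmetic: abutting read and region do not overlap).
#'
#' @param pcrs GRanges of pCRs (named or with `id` column).
#' @param readsBySample named list of GRanges, one per sample.
#' @param sampleData optional data.frame of per-sample metadata (see
#'   [EnhancerCounts()]); defaults to placeholder metadata.
#' @return an [EnhancerCounts-class] object (rows = pCRs).
#' @export
countReads <- function(pcrs, readsBySample, sampleData = NULL) {
    stopifnot(is.list(readsBySample), !is.null(names(readsBySample)))
    counts <- vapply(readsBySample, function(rd) {
        if (length(rd) == 0L)
            warning("sample with zero reads; column kept")
        countOverlaps(pcrs, rd, minoverlap = 1L, ignore.strand = TRUE)
    }, integer(length(pcrs)))
    counts <- matrix(counts, nrow = length(pcrs),
                     dimnames = list(
                         if (!is.null(pcrs$id)) pcrs$id else names(pcrs),
                         names(readsBySample)))
    if (is.null(sampleData)) {
        ns <- length(readsBySample)
        sampleData <- data.frame(mark = rep("unknown", ns),
                                 time_point = rep("unknown", ns),
                                 brain_region = rep("unknown", ns),
                                 row.names = names(readsBySample))
    }
    EnhancerCounts(counts, rowRanges = granges(pcrs),
                   sampleData = sampleData)
}

## ---- TMM -------------------------------------------------------------------

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' For every sample against a reference sample, per-region log ratios
#' `M = log2((y_j/N_j)/(y_r/N_r))` and abundances
#' `A = 0.5*log2((y_j/N_j)*(y_r/N_r))` are computed over regions with finite
#' values, doubly trimmed (`logratioTrim` of the M distribution and
#' `absTrim` of the A distribution removed from each tail), and the factor
#' is `2^` the precision-weighted mean of the retained M values, with
#' weights the inverse delta-method variances
#' `(N_j - y_j)/(N_j*y_j) + (N_r - y_r)/(N_r*y_r)`. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts numeric matrix (regions x samples) or
#'   [EnhancerCounts-class].
#' @param reference column index/name of the reference sample, or `NULL` to
#'   pick the sample whose upper-quartile count fraction is closest to the
#'   mean upper-quartile fraction.
#' @param logratioTrim,absTrim tail fractions trimmed from the M and A
#'   distributions (defaults 0.30 and 0.05).
#' @param aCutoff lower bound on A below which regions are discarded.
#' @return named numeric vector of factors `f_j`, geometric mean 1.
#' @export
tmmFactors <- function(counts, reference = NULL, logratioTrim = 0.3,
                       absTrim = 0.05, aCutoff = -1e10) {
    m <- if (is(counts, "EnhancerCounts")) countsMatrix(counts)
         else as.matrix(counts)
    if (ncol(m) < 2L) stop("TMM needs at least two samples")
    lib <- colSums(m)
    if (any(lib <= 0)) stop("every sample needs positive total counts")
    if (is.null(reference)) {
        f75 <- apply(m, 2L, function(x) stats::quantile(x, 0.75)) / lib
        reference <- which.min(abs(f75 - mean(f75)))
    }
    ref <- m[, reference]
    nR <- lib[reference]
    f <- vapply(seq_len(ncol(m)), function(j) {
        .tmmPair(m[, j], ref, lib[j], nR, logratioTrim, absTrim, aCutoff)
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(m)
    f
}

.tmmPair <- function(obs, ref, nO, nR, logratioTrim, absTrim, aCutoff) {
    logR <- log2((obs / nO) / (ref / nR))
    absE <- (log2(obs / nO) + log2(ref / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
    fin <- is.finite(logR) & is.finite(absE) & (absE > aCutoff)
    if (!any(fin)) stop("no region with finite M vs the reference sample")
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * absTrim) + 1
    hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
            rank(absE) >= loS & rank(absE) <= hiS
    f <- 2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
    if (!is.finite(f)) f <- 1
    f
}

## ---- replicate grouping ----------------------------------------------------

#' Group samples into replicate groups by correlation
#'
#' Samples without a declared `replicate_group` are merged (within their
#' mark, in column order) into the existing group whose mean log-scale
#' normalized profile they correlate with best, provided the Pearson
#' correlation exceeds `threshold`; otherwise they start a singleton group.
#'
#' @param ec an [EnhancerCounts-class] object.
#' @param threshold correlation threshold (default 0.89).
#' @return `ec` with `replicate_group` filled in for all samples.
#' @export
groupReplicates <- function(ec, threshold = 0.89) {
    m <- countsMatrix(ec)
    f <- tmmFactors(m)
    logn <- log2(t(t(m) / (colSums(m) * f)) * 1e6 + 0.5)
    cd <- colData(ec)
    grp <- as.character(cd$replicate_group)
    for (mark in unique(cd$mark)) {
        idx <- which(cd$mark == mark)
        for (j in idx[is.na(grp[idx])]) {
            groups <- unique(stats::na.omit(grp[idx]))
            best <- NA_character_; bestR <- -Inf
            for (g in groups) {
                prof <- rowMeans(logn[, idx[!is.na(grp[idx]) &
                                            grp[idx] == g], drop = FALSE])
                r <- stats::cor(logn[, j], prof)
                if (!is.na(r) && r > bestR) { bestR <- r; best <- g }
            }
            grp[j] <- if (!is.na(best) && bestR > threshold) best
                      else paste0(mark, "_grp", sum(cd$mark == mark &
                                                    !is.na(grp)) + j)
        }
    }
    cd$replicate_group <- grp
    colData(ec) <- cd
    ec
}

## ---- NB GLM machinery ------------------------------------------------------

.nbLoglik <- function(y, mu, phi) {
    if (phi < 1e-10) sum(stats::dpois(y, mu, log = TRUE))
    else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Negative binomial deviance
#'
#' `2 * sum(y*log(y/mu) - (y + 1/phi)*log((1 + phi*y)/(1 + phi*mu)))`, with
#' the `y*log(y/mu)` term taken as 0 when `y = 0`; the Poisson deviance is
#' the `phi -> 0` limit.
#'
#' @param y,mu observed counts and fitted means (vectors or matrices).
#' @param phi NB dispersion (variance = mu + phi*mu^2).
#' @return deviance summed over vector elements (or per-row for matrices).
#' @export
nbDeviance <- function(y, mu, phi) {
    yl <- ifelse(y > 0, y * log(y / mu), 0)
    d <- if (phi < 1e-10) 2 * (yl - (y - mu))
         else 2 * (yl - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
    if (is.matrix(y)) rowSums(d) else sum(d)
}

#' Fit a negative-binomial log-linear GLM to one count row
#'
#' Iteratively reweighted least squares with log link and offsets;
#' convergence when the largest coefficient change falls below `tol` or
#' after `maxIter` iterations (non-convergence is flagged, and downstream
#' tests treat flagged fits conservatively with p = 1).
#'
#' @param y integer count vector.
#' @param design full-column-rank design matrix (rows = samples).
#' @param offsets per-sample log effective library sizes.
#' @param dispersion NB dispersion `phi`.
#' @param tol,maxIter convergence controls.
#' @return list with `beta`, `mu`, `deviance`, `df.residual`, `converged`.
#' @export
fitNbGlm <- function(y, design, offsets, dispersion, tol = 1e-8,
                     maxIter = 50L) {
    X <- as.matrix(design)
    if (qr(X)$rank < ncol(X)) stop("design matrix not of full column rank")
    beta <- qr.solve(X, log(pmax(y, 0.5)) - offsets)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        eta <- drop(X %*% beta) + offsets
        mu <- pmin(exp(eta), 1e12)
        w <- mu / (1 + dispersion * mu)
        z <- (eta - offsets) + (y - mu) / mu
        fit <- stats::lm.wfit(X, z, w)
        delta <- fit$coefficients - beta
        beta <- fit$coefficients
        if (max(abs(delta)) < tol) { converged <- TRUE; break }
    }
    mu <- pmin(drop(exp(X %*% beta + offsets)), 1e12)
    list(beta = beta, mu = mu,
         deviance = nbDeviance(y, mu, dispersion),
         df.residual = length(y) - ncol(X), converged = converged)
}

## Vectorized group-mean NB fit for one-way layouts (intercept + one
## factor). For each (region, group) cell the MLE solves the scalar score
## equation sum((y - mu)/(1 + phi*mu)) = 0 with mu = exp(beta + offset),
## solved by Newton iterations carried element-wise across all regions.
.fitNbOneWay <- function(Y, group, offsets, phi, maxIter = 60L,
                         tol = 1e-10) {
    Y <- as.matrix(Y)
    G <- nrow(Y)
    mu <- matrix(0, G, ncol(Y))
    logdet <- numeric(G)
    for (g in levels(group)) {
        j <- which(group == g)
        Yg <- Y[, j, drop = FALSE]
        eo <- exp(offsets[j])
        beta <- log(pmax(rowSums(Yg), 0.25) / sum(eo))
        for (it in seq_len(maxIter)) {
            Mu <- exp(outer(beta, offsets[j], "+"))
            sc <- rowSums((Yg - Mu) / (1 + phi * Mu))
            info <- rowSums(Mu * (1 + phi * Yg) / (1 + phi * Mu)^2)
            step <- sc / pmax(info, 1e-12)
            step <- pmax(pmin(step, 5), -5)
            beta <- beta + step
            if (max(abs(step)) < tol) break
        }
        Mu <- exp(outer(beta, offsets[j], "+"))
        mu[, j] <- Mu
        W <- Mu / (1 + phi * Mu)
        logdet <- logdet + log(pmax(rowSums(W), 1e-300))
    }
    dev <- nbDeviance(Y, mu, phi)
    list(mu = mu, deviance = dev,
         df.residual = ncol(Y) - nlevels(group), logdet = logdet)
}

.rowNbLoglik <- function(Y, mu, phi) {
    if (phi < 1e-10)
        rowSums(stats::dpois(Y, mu, log = TRUE))
    else
        rowSums(stats::dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Estimate a common NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' Maximizes, over the dispersion `phi`, the adjusted profile likelihood
#' summed over regions: the NB log-likelihood at the per-region group-mean
#' fit minus half the log determinant of the Fisher information of the
#' fitted coefficients. The search is a log10-scale grid followed by
#' golden-section refinement (`stats::optimize`), clipped to
#' `[1e-8, 10]`.
#'
#' @param counts count matrix (regions x samples) or
#'   [EnhancerCounts-class].
#' @param group factor of design-cell membership (one-way layout: the
#'   factor levels crossed with the intercept).
#' @param offsets per-sample log effective library sizes; default
#'   `log(colSums(counts))`.
#' @return the estimated dispersion `phi`.
#' @export
estimateCommonDispersion <- function(counts, group, offsets = NULL) {
    Y <- if (is(counts, "EnhancerCounts")) countsMatrix(counts)
         else as.matrix(counts)
    group <- droplevels(as.factor(group))
    if (ncol(Y) - nlevels(group) < 1L)
        stop("dispersion inestimable: zero residual degrees of freedom")
    if (is.null(offsets)) offsets <- log(colSums(Y))
    apl <- function(log10phi) {
        phi <- 10^log10phi
        fit <- .fitNbOneWay(Y, group, offsets, phi)
        sum(.rowNbLoglik(Y, fit$mu, phi)) - 0.5 * sum(fit$logdet)
    }
    grid <- seq(-6, 1, by = 0.5)
    vals <- vapply(grid, apl, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(apl, c(lo, hi), maximum = TRUE, tol = 1e-4)
    phi <- 10^opt$maximum
    ## a flat APL up to the lower grid edge means effectively Poisson
    if (vals[1L] >= max(vals) - 1e-6) phi <- 1e-8
    min(max(phi, 1e-8), 10)
}

## Inverse of the trigamma function by Newton iteration (monotone
## decreasing on (0, Inf)), used to moment-match the prior degrees of
## freedom of the quasi-dispersion distribution.
.trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, 2L)
        x <- x + dif
        if (-dif / x < 1e-8) break
    }
    x
}

## Empirical-Bayes estimate of (prior df d0, prior value s0) for scaled-F
## distributed quasi-dispersions s2 on df residual degrees of freedom.
.estimatePriorDf <- function(s2, df) {
    ok <- s2 > 1e-12
    if (sum(ok) < 10L) return(list(d0 = 10, s0 = mean(s2)))
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e) - trigamma(df / 2)
    if (is.na(evar) || evar <= 0)
        return(list(d0 = Inf, s0 = exp(mean(e))))
    d0 <- 2 * .trigammaInverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0 = s0)
}

#' Quasi-likelihood F-test between nested NB-GLM fits
#'
#' Per region the quasi-dispersion `s2 = deviance_full/df_full` is shrunk
#' toward a common value with `priorDf` pseudo-degrees of freedom,
#' `s2_mod = (priorDf*s2_prior + df*s2)/(priorDf + df)`, and the statistic
#' is `F = ((deviance_null - deviance_full)/dfTest)/s2_mod`, referred to an
#' F distribution on `(dfTest, df + priorDf)` degrees of freedom. By
#' default (`priorDf = "auto"`) the prior degrees of freedom and the prior
#' value are estimated empirically by moment-matching the scaled-F
#' distribution of the quasi-dispersions (consistent residual variation
#' then yields a large prior and near-chi-squared behaviour); a numeric
#' `priorDf` fixes the pseudo-degrees and shrinks toward the mean
#' quasi-dispersion. Regions with a non-converged full fit get `p = 1`.
#'
#' @param full,null lists with elements `deviance` (vector over regions) and
#'   `df.residual` (scalar), as returned by the fitting functions; `full`
#'   may also carry a logical `converged` vector.
#' @param priorDf `"auto"` (default) or a positive number of prior degrees
#'   of freedom.
#' @return `data.frame` with columns `F` and `p`; attributes `priorDf` and
#'   `priorValue` record the shrinkage target.
#' @export
qlFTest <- function(full, null, priorDf = "auto") {
    dfFull <- full$df.residual
    dfTest <- null$df.residual - dfFull
    if (dfTest <= 0L) stop("null design must be nested in the full design")
    if (dfFull < 1L) stop("no residual degrees of freedom in the full fit")
    s2 <- pmax(full$deviance / dfFull, 0)
    if (identical(priorDf, "auto")) {
        pri <- .estimatePriorDf(s2, dfFull)
        d0 <- pri$d0; s0 <- pri$s0
    } else {
        d0 <- as.numeric(priorDf); s0 <- mean(s2)
    }
    s2mod <- if (is.finite(d0)) (d0 * s0 + dfFull * s2) / (d0 + dfFull)
             else rep(s0, length(s2))
    Fstat <- pmax((null$deviance - full$deviance) / dfTest, 0) / s2mod
    p <- stats::pf(Fstat, dfTest, dfFull + d0, lower.tail = FALSE)
    if (!is.null(full$converged)) p[!full$converged] <- 1
    out <- data.frame(F = Fstat, p = p)
    attr(out, "priorDf") <- d0
    attr(out, "priorValue") <- s0
    out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of p values in `[0, 1]`.
#' @return vector of monotone BH-adjusted q values.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Pool per-analysis calls into DAE/nDAE labels
#'
#' A region is labelled `DAE` iff its FDR falls below `alpha` in at least
#' `minAnalyses` distinct (mark x factor) analyses.
#'
#' @param calls `data.frame`/`DataFrame` with columns `pcr_id`, `analysis`,
#'   `fdr`.
#' @param alpha FDR threshold (default 0.05).
#' @param minAnalyses pooling threshold (default 2).
#' @return `DataFrame` with `pcr_id`, `n_significant_analyses`, `label`.
#' @export
callDaes <- function(calls, alpha = 0.05, minAnalyses = 2L) {
    calls <- as.data.frame(calls)
    ids <- unique(calls$pcr_id)
    sig <- calls[calls$fdr < alpha, , drop = FALSE]
    nsig <- tapply(sig$analysis, factor(sig$pcr_id, levels = ids),
                   function(a) length(unique(a)))
    nsig[is.na(nsig)] <- 0L
    nsig <- unname(as.integer(nsig))
    DataFrame(pcr_id = ids,
              n_significant_analyses = nsig,
              label = ifelse(nsig >= minAnalyses, "DAE", "nDAE"))
}

#' Run the full differential-activity analysis
#'
#' For every epigenome mark and every design factor (`time_point`,
#' `brain_region`) with at least two levels among that mark's samples:
#' subsets the samples, computes TMM offsets, estimates a common Cox-Reid
#' dispersion, fits the group-mean (full) and intercept-only (null) NB
#' GLMs, applies the quasi-likelihood F-test, and BH-adjusts within the
#' analysis. Calls from all analyses are pooled with [callDaes()].
#'
#' @param ec an [EnhancerCounts-class] object.
#' @param alpha FDR threshold (default 0.05).
#' @param minAnalyses pooling threshold (default 2).
#' @param priorDf QL shrinkage prior degrees of freedom: `"auto"`
#'   (empirical-Bayes estimate, the default) or a positive number.
#' @return a [DifferentialActivity-class] object.
#' @export
runDifferentialActivity <- function(ec, alpha = 0.05, minAnalyses = 2L,
                                    priorDf = "auto") {
    cd <- colData(ec)
    Y <- countsMatrix(ec)
    ids <- rownames(Y)
    allCalls <- list()
    disps <- numeric()
    for (mark in unique(cd$mark)) {
        jm <- which(cd$mark == mark)
        for (fac in c("time_point", "brain_region")) {
            lev <- droplevels(as.factor(cd[[fac]][jm]))
            if (nlevels(lev) < 2L) next
            if (ncol(Y[, jm, drop = FALSE]) - nlevels(lev) < 1L) next
            Ym <- Y[, jm, drop = FALSE]
            f <- tmmFactors(Ym)
            offs <- log(colSums(Ym) * f)
            phi <- estimateCommonDispersion(Ym, lev, offs)
            fullFit <- .fitNbOneWay(Ym, lev, offs, phi)
            nullFit <- .fitNbOneWay(Ym, factor(rep("all", length(jm))),
                                    offs, phi)
            ft <- qlFTest(fullFit, nullFit, priorDf = priorDf)
            analysis <- paste(mark, fac, sep = ":")
            disps[analysis] <- phi
            allCalls[[analysis]] <- data.frame(
                pcr_id = ids, analysis = analysis, F = ft$F, p = ft$p,
                fdr = bhAdjust(ft$p))
        }
    }
    if (!length(allCalls)) stop("no analysis with >= 2 factor levels")
    calls <- do.call(rbind, allCalls)
    calls$significant <- calls$fdr < alpha
    labels <- callDaes(calls, alpha = alpha, minAnalyses = minAnalyses)
    new("DifferentialActivity", calls = DataFrame(calls, row.names = NULL),
        labels = labels, alpha = alpha,
        minAnalyses = as.integer(minAnalyses), dispersions = disps)
}
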