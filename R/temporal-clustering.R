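## Temporal clustering of DAEs: Spearman distance, PAM (k-medoids) with
## BUILD+SWAP, silhouette widths, and bootstrap silhouette-guided selection
## of the number of clusters.

#' Spearman distance matrix between rows
#'
#' `d(i, j) = 1 - rho(i, j)` with `rho` the Spearman rank correlation
#' (average ranks for ties), so `d` lies in `[0, 2]` with 0 on the
#' diagonal. Rows with zero rank variance (constant rows) have undefined
#' correlation; their distance is set to 1 against all non-identical rows
#' (0 against identical ones), with a warning.
#'
#' @param mat numeric matrix, rows = objects (e.g. DAEs), columns =
#'   features (log2-scaled normalized counts); at least 2 columns.
#' @return symmetric distance matrix.
#' @export
spearmanDistance <- function(mat) {
    mat <- as.matrix(mat)
    if (ncol(mat) < 2L) stop("need at least two feature columns")
    rho <- suppressWarnings(stats::cor(t(mat), method = "spearman"))
    d <- 1 - rho
    if (any(is.na(d))) {
        warning("constant row(s): distance set to 1 vs non-identical rows")
        same <- function(i, j) all(mat[i, ] == mat[j, ])
        for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d)))
            if (is.na(d[i, j])) d[i, j] <- if (same(i, j)) 0 else 1
    }
    diag(d) <- 0
    d
}

#' k-medoids (PAM) clustering on a precomputed distance matrix
#'
#' Greedy BUILD initialization followed by best-improvement SWAP until no
#' medoid swap decreases the total cost (sum of distances of every object
#' to its medoid), as implemented by `cluster::pam` on a dissimilarity
#' object. Instances with at most 10 rows are instead solved exactly by
#' enumerating all medoid subsets (the SWAP heuristic can terminate in a
#' local optimum on such tiny inputs, where exhaustive search is free).
#' The procedure is deterministic; `seed` is accepted for interface
#' stability and ignored. Ties are broken toward the lexicographically
#' smallest medoid set.
#'
#' @param dist symmetric distance matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed unused (PAM on a fixed distance matrix is deterministic).
#' @return list with `k`, `medoids` (row indices), `assignment` (integer
#'   vector), `cost` (sum of within-cluster distances to medoids) and
#'   `silhouette` (per-row widths, `NA` for `k = 1`).
#' @export
pamCluster <- function(dist, k, seed = NULL) {
    d <- as.matrix(dist)
    n <- nrow(d)
    if (k > n) stop("k must not exceed the number of rows")
    if (k == n) {
        return(list(k = k, medoids = seq_len(n), assignment = seq_len(n),
                    cost = 0, silhouette = rep(0, n)))
    }
    if (n <= 10L) {
        subsets <- utils::combn(n, k)
        costs <- apply(subsets, 2L, function(s)
            sum(apply(d[, s, drop = FALSE], 1L, min)))
        medoids <- as.integer(subsets[, which.min(costs)])
        assignment <- as.integer(medoids[
            apply(d[, medoids, drop = FALSE], 1L, which.min)])
        assignment <- match(assignment, medoids)
    } else {
        fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE,
                            keep.diss = FALSE, keep.data = FALSE)
        assignment <- as.integer(fit$clustering)
        medoids <- as.integer(fit$id.med)
    }
    cost <- sum(d[cbind(seq_len(n), medoids[assignment])])
    sil <- if (k >= 2L) silhouetteWidths(d, assignment)$widths
           else rep(NA_real_, n)
    list(k = k, medoids = medoids, assignment = assignment, cost = cost,
         silhouette = sil)
}

#' Silhouette widths of a clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance
#' of `i` to its own cluster (excluding itself) and `b(i)` the smallest
#' mean distance to any other cluster; members of singleton clusters get
#' `s(i) = 0`.
#'
#' @param dist symmetric distance matrix.
#' @param assignment integer cluster labels (at least 2 clusters).
#' @return list with `widths` (per-row) and `mean`.
#' @export
silhouetteWidths <- function(dist, assignment) {
    d <- as.matrix(dist)
    if (length(unique(assignment)) < 2L)
        stop("silhouette needs at least two clusters")
    sil <- cluster::silhouette(as.integer(factor(assignment)), dmatrix = d)
    widths <- as.numeric(sil[, "sil_width"])
    list(widths = widths, mean = mean(widths))
}

#' Choose the number of clusters by bootstrapped silhouette
#'
#' For each bootstrap resample of the rows (unique resampled indices), the
#' `k` in `kRange` maximizing the mean silhouette of the PAM clustering is
#' recorded; the majority-vote `k` across resamples is returned, smaller
#' `k` winning ties.
#'
#' @param dist symmetric distance matrix.
#' @param kRange candidate numbers of clusters (default `2:6`).
#' @param nBoot number of bootstrap resamples (default 100).
#' @param seed RNG seed for the resampling.
#' @return the selected `k`.
#' @export
selectK <- function(dist, kRange = 2:6, nBoot = 100L, seed = 1L) {
    d <- as.matrix(dist)
    n <- nrow(d)
    if (all(d == 0)) stop("degenerate input: all rows identical")
    kRange <- kRange[kRange >= 2L & kRange <= n - 1L]
    if (!length(kRange)) stop("kRange outside [2, n-1]")
    if (length(kRange) == 1L) return(kRange)
    set.seed(seed)
    votes <- integer(0)
    for (b in seq_len(nBoot)) {
        idx <- sort(unique(sample.int(n, n, replace = TRUE)))
        if (length(idx) <= max(kRange)) idx <- seq_len(n)
        db <- d[idx, idx]
        msil <- vapply(kRange, function(k)
            mean(pamCluster(db, k)$silhouette), numeric(1))
        votes <- c(votes, kRange[which.max(msil)])
    }
    tab <- table(votes)
    as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1L])
}
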