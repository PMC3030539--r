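#' Log2-transform a raw profile matrix
#'
#' @param x a \linkS4class{MetaboliteProfiles} on the raw scale; all
#'   non-missing values must be positive. Missing values are preserved.
#' @return The object with values log2-transformed and
#'   \code{profileScale(x) == "log2"}.
#' @export
log2Transform <- function(x) {
    stopIfNot(profileScale(x) == "raw",
              "profiles are already on the log2 scale")
    m <- profileValues(x)
    bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf("non-positive value(s) cannot be log2-transformed: %s",
             paste(sprintf("[%s, %s]", rownames(m)[bad[, 1]],
                           colnames(m)[bad[, 2]]), collapse = ", ")),
             call. = FALSE)
    }
    MetaboliteProfiles(log2(m), groups = unname(sampleGroups(x)),
                       tissue = unname(sampleTissue(x)), scale = "log2")
}

# Column-wise ranks of a matrix of random keys: one order() call per draw.
# Each column is a uniform random permutation of 1..n when keys are iid
# uniform.
.columnRanks <- function(u) {
    n <- nrow(u); K <- ncol(u)
    rk <- integer(n * K)
    rk[order(col(u), u)] <- rep(seq_len(n), K)
    matrix(rk, n, K)
}

#' Rank-product test for differential metabolite abundance
#'
#' Two-group rank product over all cross-group sample pairs: for each of
#' the \eqn{n_a \times n_b} pairs the per-metabolite log-ratios are ranked
#' (rank 1 = most up-regulated for the "up" analysis, most down-regulated
#' for "down"; ties get average ranks) and
#' \eqn{RP_g = (\prod_k rank_{g,k})^{1/K}}. The null distribution comes
#' from \code{nPerm} random permutations of each metabolite's values
#' across the tested samples (recomputing all cross-pair ratios and ranks
#' per permutation). Permuting the data rather than drawing independent
#' ranks per pair is essential: the \eqn{K} cross pairs reuse the same
#' samples and are strongly dependent, and a null that ignores this is
#' badly anti-conservative. The estimated false-discovery proportion is
#' \eqn{pfp(g) = E[\#\, null\ RP \le RP_g] / rank(RP_g)} (uncapped, with a
#' capped convenience column).
#'
#' @param x a \linkS4class{MetaboliteProfiles} on the log2 scale with no
#'   missing values in the tested samples.
#' @param groupA,groupB group labels; ratios are A - B, so "up" means
#'   higher in \code{groupA}.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the permutation null.
#' @return data.frame: metabolite, direction ("up"/"down"), RP, pfp,
#'   pfpCapped, nPerm.
#' @export
rankProductTest <- function(x, groupA, groupB, nPerm = 1000L, seed) {
    stopIfNot(nPerm >= 1, "nPerm must be >= 1")
    stopIfNot(!missing(seed), "'seed' is required")
    if (profileScale(x) != "log2")
        warning("rank product expects log2-scale profiles")
    g <- sampleGroups(x)
    ia <- which(g == groupA); ib <- which(g == groupB)
    stopIfNot(length(ia) >= 2 && length(ib) >= 2,
              "both groups need >= 2 samples (got %d and %d)",
              length(ia), length(ib))
    m <- profileValues(x)[, c(ia, ib), drop = FALSE]
    stopIfNot(!anyNA(m), "rank product requires complete rows; %d missing value(s) present",
              sum(is.na(m)))
    a <- profileValues(x)[, ia, drop = FALSE]
    b <- profileValues(x)[, ib, drop = FALSE]
    n <- nrow(a)
    # log-ratios for every cross-group pair: n x (n_a * n_b)
    ratios <- a[, rep(seq_along(ia), times = length(ib)), drop = FALSE] -
              b[, rep(seq_along(ib), each = length(ia)), drop = FALSE]
    K <- ncol(ratios)
    logRP <- function(rk) rowMeans(log(rk))
    rankUp <- apply(-ratios, 2, rank, ties.method = "average")
    rankDown <- apply(ratios, 2, rank, ties.method = "average")
    obs <- list(up = exp(logRP(rankUp)), down = exp(logRP(rankDown)))

    x <- cbind(a, b)
    idxA <- rep(seq_along(ia), times = length(ib))
    idxB <- length(ia) + rep(seq_along(ib), each = length(ia))
    nullLog <- withSeed(as.integer(seed), {
        out <- numeric(nPerm * n)
        for (bIdx in seq_len(nPerm)) {
            xp <- t(apply(x, 1, sample))
            nullRatios <- xp[, idxA, drop = FALSE] - xp[, idxB, drop = FALSE]
            rk <- .columnRanks(-nullRatios)
            out[((bIdx - 1) * n + 1):(bIdx * n)] <- logRP(rk)
        }
        out
    })
    nullSorted <- sort(nullLog)

    res <- lapply(names(obs), function(dir) {
        rp <- obs[[dir]]
        # E[# null RP <= RP_g] per null dataset
        cnt <- findInterval(log(rp), nullSorted) / nPerm
        pfp <- cnt / rank(rp, ties.method = "average")
        data.frame(metabolite = rownames(a), direction = dir, RP = rp,
                   pfp = pfp, pfpCapped = pmin(1, pfp),
                   nPerm = as.integer(nPerm), row.names = NULL)
    })
    do.call(rbind, res)
}

#' Principal component analysis of a profile matrix
#'
#' Singular value decomposition of the column-centered (optionally
#' unit-variance scaled) samples x metabolites matrix. Metabolites with
#' missing values are dropped with a message; constant metabolites are
#' dropped when scaling.
#'
#' @param x a \linkS4class{MetaboliteProfiles}.
#' @param nComponents number of components to return (default
#'   \code{min(dim)}).
#' @param scale. unit-variance scale each metabolite (default TRUE, common
#'   for metabolomics where ranges are heterogeneous).
#' @return list of class \code{"ProfilePCA"}: \code{scores} (samples x
#'   components), \code{loadings} (metabolites x components),
#'   \code{explainedVarianceRatio}.
#' @export
pcaProfiles <- function(x, nComponents = NULL, scale. = TRUE) {
    m <- profileValues(x)
    drop <- apply(m, 1, anyNA)
    if (any(drop)) {
        message(sprintf("dropping %d metabolite(s) with missing values for PCA",
                        sum(drop)))
        m <- m[!drop, , drop = FALSE]
    }
    if (scale.) {
        cst <- apply(m, 1, stats::sd) == 0
        if (any(cst)) {
            message(sprintf("dropping %d constant metabolite(s) for scaled PCA",
                            sum(cst)))
            m <- m[!cst, , drop = FALSE]
        }
    }
    X <- t(m)
    if (is.null(nComponents)) nComponents <- min(dim(X))
    stopIfNot(nComponents >= 1 && nComponents <= min(dim(X)),
              "nComponents must be in [1, %d]", min(dim(X)))
    pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
    k <- min(nComponents, ncol(pc$x))
    evr <- pc$sdev^2 / sum(pc$sdev^2)
    structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                   loadings = pc$rotation[, seq_len(k), drop = FALSE],
                   explainedVarianceRatio = evr[seq_len(k)],
                   center = pc$center, scale = pc$scale),
              class = "ProfilePCA")
}
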