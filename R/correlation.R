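#' Spearman rank correlations for all metabolite pairs
#'
#' For every unordered pair the Spearman coefficient is the Pearson
#' correlation of within-pair ranks (average ranks for ties) over
#' pairwise-complete samples, with the per-pair sample count recorded.
#' Pairs with fewer than 4 complete samples, or with a constant metabolite,
#' get a missing \code{r} and are excluded from testing (a warning reports
#' how many). The t statistic and two-sided p-value of the no-correlation
#' test are attached per pair (\code{\link{correlationPvalue}}).
#'
#' @param x a \linkS4class{MetaboliteProfiles}.
#' @param sampleSubset optional character vector of sample ids (or logical/
#'   integer index); e.g. one genotype's samples. Needs >= 4 samples.
#' @return data.frame with one row per unordered pair: \code{u}, \code{v},
#'   \code{r}, \code{n}, \code{t}, \code{p}. The full metabolite id set is
#'   kept in \code{attr(, "metabolites")} and the subset size in
#'   \code{attr(, "nSamples")}.
#' @export
spearmanCorrelations <- function(x, sampleSubset = NULL) {
    m <- profileValues(x)
    if (!is.null(sampleSubset)) m <- m[, sampleSubset, drop = FALSE]
    stopIfNot(ncol(m) >= 4, "need >= 4 samples (got %d)", ncol(m))
    tm <- t(m)
    cm <- suppressWarnings(
        stats::cor(tm, method = "spearman", use = "pairwise.complete.obs"))
    nm <- crossprod(!is.na(tm))
    out <- pairsFromMatrix(cm)
    names(out)[3] <- "r"
    out$n <- nm[upper.tri(nm)]
    tooFew <- !is.na(out$r) & out$n < 4
    out$r[out$n < 4] <- NA_real_
    nExcl <- sum(is.na(out$r))
    if (nExcl)
        warning(sprintf(
            "%d pair(s) excluded from testing (n < 4 or zero rank variance)",
            nExcl))
    tp <- correlationPvalue(out$r, out$n)
    out$t <- tp$t
    out$p <- tp$p
    attr(out, "metabolites") <- rownames(m)
    attr(out, "nSamples") <- ncol(m)
    out
}

#' Test a correlation against the hypothesis of no correlation
#'
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, two-sided p from Student t with
#' \eqn{n-2} degrees of freedom. \eqn{|r| = 1} gives \eqn{p = 0} by
#' convention (reported via message). Vectorized; NA in, NA out.
#'
#' @param r correlation coefficient(s).
#' @param n sample size(s), >= 4.
#' @return data.frame with columns \code{t} and \code{p}.
#' @export
correlationPvalue <- function(r, n) {
    stopIfNot(length(r) == length(n) || length(n) == 1,
              "'n' must match 'r' or be scalar")
    n <- rep_len(n, length(r))
    ok <- !is.na(r)
    stopIfNot(all(n[ok] >= 4), "every tested pair needs n >= 4")
    t <- p <- rep(NA_real_, length(r))
    perfect <- ok & abs(r) >= 1
    if (any(perfect)) {
        message(sprintf("%d perfect correlation(s): p = 0 by convention",
                        sum(perfect)))
        t[perfect] <- sign(r[perfect]) * Inf
        p[perfect] <- 0
    }
    reg <- ok & !perfect
    t[reg] <- r[reg] * sqrt((n[reg] - 2) / (1 - r[reg]^2))
    p[reg] <- 2 * stats::pt(-abs(t[reg]), df = n[reg] - 2)
    data.frame(t = t, p = p)
}

# Least concave majorant of points (x, y) with x strictly increasing:
# returns the hull vertex indices. Standard monotone-chain upper hull.
.lcmHull <- function(x, y) {
    n <- length(x)
    hull <- integer(n)
    h <- 0L
    for (i in seq_len(n)) {
        while (h >= 2L) {
            a <- hull[h - 1L]; b <- hull[h]
            # drop b if it lies on or below chord a--i (keep hull concave)
            if ((y[b] - y[a]) * (x[i] - x[a]) <= (y[i] - y[a]) * (x[b] - x[a]))
                h <- h - 1L else break
        }
        h <- h + 1L
        hull[h] <- i
    }
    hull[seq_len(h)]
}

#' Local false discovery rate from p-values
#'
#' Two-component mixture \eqn{f(p) = \eta_0 \cdot 1 + (1-\eta_0) h(p)}:
#' \eqn{\eta_0} is estimated as the fraction of p-values above
#' \eqn{\lambda = 0.5} divided by 0.5 (capped at 1); the marginal density
#' \eqn{\hat f} by the Grenander nonincreasing density estimator (slope of
#' the least concave majorant of the empirical CDF, with anchors at (0,0)
#' and (1,1)); and \eqn{fdr(p) = \min(1, \eta_0/\hat f(p))}. Pipeline
#' significance calls use fdr < 0.05.
#'
#' @param p numeric vector of p-values in [0,1]; NAs propagate.
#' @param lambda tail cutoff for the null-proportion estimate (default 0.5).
#' @return numeric vector of local fdr values, same length as \code{p}.
#' @export
localFdr <- function(p, lambda = 0.5) {
    stopIfNot(length(p) > 0, "empty p-value input")
    ok <- !is.na(p)
    pv <- p[ok]
    stopIfNot(length(pv) > 0, "no non-missing p-values")
    stopIfNot(all(pv >= 0 & pv <= 1), "p-values must lie in [0,1]")
    if (length(pv) < 50)
        warning(sprintf("only %d p-values; local fdr is unreliable below ~50",
                        length(pv)))
    m <- length(pv)
    eta0 <- min(1, mean(pv > lambda) / (1 - lambda))

    sp <- sort(pv)
    ux <- unique(sp)
    Fy <- cumsum(tabulate(match(sp, ux), nbins = length(ux))) / m
    gx <- c(0, ux); gy <- c(0, Fy)
    if (ux[length(ux)] < 1) { gx <- c(gx, 1); gy <- c(gy, 1) }
    else gy[length(gy)] <- 1
    hull <- .lcmHull(gx, gy)
    hx <- gx[hull]; hy <- gy[hull]
    slopes <- diff(hy) / diff(hx)
    # f-hat(p): slope of the hull segment containing p (left-continuous)
    seg <- pmax(1L, findInterval(pv, hx, rightmost.closed = TRUE,
                                 left.open = TRUE))
    seg <- pmin(seg, length(slopes))
    fhat <- slopes[seg]
    fdr <- pmin(1, eta0 / pmax(fhat, .Machine$double.eps))
    out <- rep(NA_real_, length(p))
    out[ok] <- fdr
    out
}

#' Fisher Z test for the difference of two correlations
#'
#' \eqn{z_i = \mathrm{atanh}(r_i)};
#' \eqn{Z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}}; two-sided
#' standard-normal p-value. Coefficients at \eqn{|r| = 1} cannot be
#' transformed: those pairs are flagged \code{NA} with a warning.
#' Vectorized.
#'
#' @param r1,r2 correlation coefficients in the two conditions.
#' @param n1,n2 per-pair sample sizes (>= 4).
#' @return data.frame: \code{z1}, \code{z2}, \code{Z}, \code{pDiff}.
#' @export
fisherZDifference <- function(r1, n1, r2, n2) {
    len <- max(length(r1), length(r2))
    r1 <- rep_len(r1, len); r2 <- rep_len(r2, len)
    n1 <- rep_len(n1, len); n2 <- rep_len(n2, len)
    ok <- !is.na(r1) & !is.na(r2)
    stopIfNot(all(n1[ok] >= 4 & n2[ok] >= 4), "need n1, n2 >= 4")
    diverged <- ok & (abs(r1) >= 1 | abs(r2) >= 1)
    if (any(diverged))
        warning(sprintf("%d pair(s) with |r| = 1 flagged NA (Fisher transform diverges)",
                        sum(diverged)))
    use <- ok & !diverged
    z1 <- z2 <- Z <- pDiff <- rep(NA_real_, len)
    z1[use] <- atanh(r1[use])
    z2[use] <- atanh(r2[use])
    Z[use] <- (z1[use] - z2[use]) /
        sqrt(1 / (n1[use] - 3) + 1 / (n2[use] - 3))
    pDiff[use] <- 2 * stats::pnorm(-abs(Z[use]))
    data.frame(z1 = z1, z2 = z2, Z = Z, pDiff = pDiff)
}

#' Differential correlation table between two conditions
#'
#' Merges two pair tables from \code{\link{spearmanCorrelations}} on their
#' common metabolite pairs, applies \code{\link{fisherZDifference}} with
#' the per-pair sample sizes, and attaches a local fdr computed across all
#' tested pairs. Columns mirror the standard differential-correlation
#' listing: pair, r1, r2, p1, p2, p(diff), r1 - r2, fdr.
#'
#' @param corA,corB pair tables for conditions 1 and 2.
#' @return data.frame: u, v, r1, r2, n1, n2, p1, p2, z1, z2, Z, pDiff,
#'   delta, fdr.
#' @export
differentialCorrelations <- function(corA, corB) {
    key <- function(d) paste(d$u, d$v, sep = "\r")
    common <- intersect(key(corA), key(corB))
    stopIfNot(length(common) > 0, "conditions share no metabolite pairs")
    a <- corA[match(common, key(corA)), ]
    b <- corB[match(common, key(corB)), ]
    fz <- fisherZDifference(a$r, a$n, b$r, b$n)
    out <- data.frame(u = a$u, v = a$v, r1 = a$r, r2 = b$r,
                      n1 = a$n, n2 = b$n, p1 = a$p, p2 = b$p,
                      z1 = fz$z1, z2 = fz$z2, Z = fz$Z, pDiff = fz$pDiff,
                      delta = a$r - b$r, row.names = NULL)
    out$fdr <- if (all(is.na(out$pDiff))) NA_real_ else localFdr(out$pDiff)
    out
}
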