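#' Build a correlation network at a threshold
#'
#' Nodes are all metabolites; an edge joins \code{u} and \code{v} iff
#' \code{r >= threshold} (positive correlations only, the default —
#' negative correlations are rare in metabolomic data and deliberately
#' excluded) or \code{|r| >= threshold} with \code{onlyPositive = FALSE}.
#' Pairs with missing \code{r} never form edges.
#'
#' @param correlations pair table from \code{\link{spearmanCorrelations}}
#'   (columns u, v, r; \code{attr(, "metabolites")} supplies the node set,
#'   or pass \code{nodes}).
#' @param threshold correlation threshold in [0, 1]; the analysis default
#'   is 0.5.
#' @param onlyPositive keep only positive correlations (default TRUE).
#' @param nodes optional character vector overriding the node set.
#' @return An undirected simple igraph with edge attribute \code{r}.
#' @export
buildNetwork <- function(correlations, threshold = 0.5, onlyPositive = TRUE,
                         nodes = NULL) {
    stopIfNot(threshold >= 0 && threshold <= 1, "threshold must be in [0,1]")
    if (is.null(nodes)) nodes <- attr(correlations, "metabolites")
    if (is.null(nodes)) nodes <- sort(unique(c(correlations$u, correlations$v)))
    keep <- !is.na(correlations$r) &
        (if (onlyPositive) correlations$r >= threshold
         else abs(correlations$r) >= threshold)
    el <- correlations[keep, c("u", "v", "r")]
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    igraph::simplify(g, edge.attr.comb = "first")
}

#' Six graph-theoretic network measures
#'
#' Graph density \eqn{2E/(N(N-1))}, global clustering coefficient
#' (transitivity: 3 x triangles / connected triples), average degree
#' \eqn{2E/N}, average shortest-path length over connected ordered pairs
#' only (the networks are disconnected at high thresholds), number of
#' connected components, and number of edges.
#'
#' @param graph an undirected igraph.
#' @return one-row data.frame: density, clusteringCoefficient,
#'   averageDegree, averagePathLength, nComponents, nEdges. Undefined
#'   values (density at N < 2, transitivity/path length of an edgeless
#'   graph) are NA.
#' @export
graphMetrics <- function(graph) {
    N <- igraph::vcount(graph)
    E <- igraph::ecount(graph)
    dens <- if (N < 2) NA_real_ else 2 * E / (N * (N - 1))
    trans <- igraph::transitivity(graph, type = "global")
    if (is.nan(trans)) trans <- NA_real_
    apl <- suppressWarnings(igraph::mean_distance(graph, directed = FALSE,
                                                  unconnected = TRUE))
    if (is.nan(apl)) apl <- NA_real_
    data.frame(density = dens, clusteringCoefficient = trans,
               averageDegree = if (N == 0) NA_real_ else 2 * E / N,
               averagePathLength = apl,
               nComponents = as.integer(igraph::components(graph)$no),
               nEdges = as.integer(E))
}

#' Randomize a profile matrix to destroy inter-metabolite correlation
#'
#' Each randomized matrix permutes every metabolite's values independently
#' across samples, preserving each metabolite's marginal distribution while
#' destroying all dependence between metabolites — the null model for the
#' topology sweep.
#'
#' @param x a \linkS4class{MetaboliteProfiles}.
#' @param nRandom number of randomized matrices (default 100).
#' @param seed integer seed.
#' @return list of \code{nRandom} matrices with the original dimnames.
#' @export
randomizeProfiles <- function(x, nRandom = 100L, seed) {
    stopIfNot(nRandom >= 1, "nRandom must be >= 1")
    stopIfNot(!missing(seed), "'seed' is required")
    m <- profileValues(x)
    withSeed(as.integer(seed), {
        lapply(seq_len(nRandom), function(k) {
            r <- t(apply(m, 1, sample))
            dimnames(r) <- dimnames(m)
            r
        })
    })
}

.metricsAcrossGrid <- function(correlations, grid, onlyPositive = TRUE) {
    do.call(rbind, lapply(grid, function(th) {
        g <- buildNetwork(correlations, th, onlyPositive = onlyPositive)
        cbind(threshold = th, graphMetrics(g))
    }))
}

#' Sweep correlation thresholds, computing network metrics
#'
#' Builds the network at every grid threshold (default 0 to 1 by 0.01) for
#' the real correlations and, when null matrices are supplied, for each
#' randomized dataset, giving the per-threshold null collection used to
#' judge where real topology departs from noise.
#'
#' @param correlations pair table from \code{\link{spearmanCorrelations}}.
#' @param nullMatrices optional list of randomized matrices from
#'   \code{\link{randomizeProfiles}}; Spearman correlations are computed
#'   per matrix.
#' @param gridStep grid spacing (default 0.01).
#' @param onlyPositive as in \code{\link{buildNetwork}}.
#' @return list of class \code{"TopologySweep"}: \code{real} (data.frame of
#'   threshold + 6 metrics), \code{null} (same plus \code{replicate}, or
#'   NULL), \code{gridStep}.
#' @export
sweepThresholds <- function(correlations, nullMatrices = NULL,
                            gridStep = 0.01, onlyPositive = TRUE) {
    grid <- seq(0, 1, by = gridStep)
    real <- .metricsAcrossGrid(correlations, grid, onlyPositive)
    null <- NULL
    if (!is.null(nullMatrices)) {
        null <- do.call(rbind, lapply(seq_along(nullMatrices), function(k) {
            mp <- MetaboliteProfiles(nullMatrices[[k]],
                                     groups = rep("null", ncol(nullMatrices[[k]])),
                                     scale = "log2")
            ct <- suppressWarnings(spearmanCorrelations(mp))
            cbind(replicate = k, .metricsAcrossGrid(ct, grid, onlyPositive))
        }))
    }
    structure(list(real = real, null = null, gridStep = gridStep),
              class = "TopologySweep")
}

#' Select the working correlation threshold from a sweep
#'
#' Locates where the connected-component count transitions from small to
#' large — the point past which weak (noise-level) correlations have
#' dropped out but correlated modules are still intact — and returns the
#' threshold at the start of the plateau that follows it: the longest
#' constant run of the component curve strictly between its starting and
#' maximum values. Correlated data typically shows a second, sharper
#' component rise at high thresholds where the modules themselves dissolve
#' (and a terminal all-isolated plateau at the maximum); anchoring on the
#' longest intermediate plateau keeps the selection between the two
#' transitions. When no such plateau of at least \code{minPlateau} grid
#' steps exists, the threshold maximizing the one-step forward difference
#' \code{nComponents(t + step) - nComponents(t)} is returned instead; ties
#' break toward the smaller threshold. A flat component curve returns
#' \code{default} with a warning. \code{override} always wins.
#'
#' @param sweep a \code{\link{sweepThresholds}} result.
#' @param default fallback threshold (0.5).
#' @param override if non-NULL, returned as-is (user override).
#' @param minPlateau minimum plateau length in grid steps (default 3).
#' @return a single threshold value.
#' @export
selectThreshold <- function(sweep, default = 0.5, override = NULL,
                            minPlateau = 3L) {
    if (!is.null(override)) return(override)
    nc <- sweep$real$nComponents
    th <- sweep$real$threshold
    diffs <- diff(nc)
    if (all(diffs <= 0)) {
        warning("flat component curve; returning default threshold")
        return(default)
    }
    runs <- rle(nc)
    starts <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
    ok <- runs$values > nc[1] & runs$values < max(nc) &
        runs$lengths >= minPlateau
    if (any(ok)) {
        best <- which(ok)[which.max(runs$lengths[ok])]
        return(th[starts[best]])
    }
    th[which.max(diffs)]
}

#' Summary table of a topology sweep
#'
#' One row per threshold with the real value and the null mean and 5/95
#' percent quantiles of each metric; plot-ready and byte-stable.
#'
#' @param sweep a \code{\link{sweepThresholds}} result.
#' @return data.frame.
#' @export
sweepTable <- function(sweep) {
    real <- sweep$real
    if (is.null(sweep$null)) return(real)
    metrics <- setdiff(colnames(real), "threshold")
    realKey <- sprintf("%.6f", real$threshold)
    agg <- lapply(metrics, function(mc) {
        byTh <- split(sweep$null[[mc]], sprintf("%.6f", sweep$null$threshold))
        data.frame(
            thKey = names(byTh),
            mean = vapply(byTh, function(v) mean(v, na.rm = TRUE), 0),
            q05 = vapply(byTh, function(v)
                stats::quantile(v, 0.05, na.rm = TRUE, names = FALSE), 0),
            q95 = vapply(byTh, function(v)
                stats::quantile(v, 0.95, na.rm = TRUE, names = FALSE), 0))
    })
    out <- real
    for (i in seq_along(metrics)) {
        a <- agg[[i]][match(realKey, agg[[i]]$thKey), ]
        out[[paste0(metrics[i], "_nullMean")]] <- a$mean
        out[[paste0(metrics[i], "_nullQ05")]] <- a$q05
        out[[paste0(metrics[i], "_nullQ95")]] <- a$q95
    }
    out
}
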