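# Independent brute-force oracles used across the suite. These stay
# deliberately naive (rank-then-Pearson, all-pairs BFS, full hypergeometric
# enumeration) so they check the implementation rather than mirror it.

# Spearman: rank the pairwise-complete observations, then Pearson.
oracleSpearman <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    stats::cor(rank(x[ok]), rank(y[ok]))
}

# Graph metrics from an adjacency matrix via breadth-first search.
oracleGraphMetrics <- function(A) {
    N <- nrow(A)
    E <- sum(A) / 2
    deg <- rowSums(A)
    # triangles and connected triples for global transitivity
    paths2 <- sum(deg * (deg - 1)) / 2
    tri <- sum(diag(A %*% A %*% A)) / 6
    trans <- if (paths2 == 0) NA_real_ else (3 * tri) / paths2
    # BFS shortest paths
    dists <- c()
    compId <- rep(NA_integer_, N)
    cid <- 0L
    for (s in seq_len(N)) {
        if (!is.na(compId[s])) next
        cid <- cid + 1L
        d <- rep(NA_integer_, N); d[s] <- 0L
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            nb <- which(A[v, ] > 0)
            for (w in nb) if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
        }
        compId[!is.na(d)] <- cid
    }
    for (s in seq_len(N)) {
        d <- rep(NA_integer_, N); d[s] <- 0L
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            for (w in which(A[v, ] > 0)) if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
        }
        dists <- c(dists, d[-s][!is.na(d[-s])])
    }
    data.frame(density = if (N < 2) NA_real_ else 2 * E / (N * (N - 1)),
               clusteringCoefficient = trans,
               averageDegree = if (N == 0) NA_real_ else 2 * E / N,
               averagePathLength = if (length(dists)) mean(dists) else NA_real_,
               nComponents = max(compId),
               nEdges = E)
}

# One-sided over-representation p-value by full enumeration of the
# hypergeometric pmf: P(X >= a) with pathway size K, cluster size k,
# universe N.
oracleHyperTail <- function(a, K, k, N) {
    xs <- max(a, 0):min(K, k)
    if (a > min(K, k)) return(0)
    sum(choose(K, xs) * choose(N - K, k - xs)) / choose(N, k)
}

# igraph -> adjacency matrix in vertex order
adjMatrixOf <- function(g) {
    as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# random undirected simple graph on n nodes
randomGraph <- function(n, pEdge) {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < pEdge]
    A[on] <- 1L
    A <- A + t(A)
    dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    A
}

graphFromAdj <- function(A) {
    igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Jaccard index between two sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small profile container shortcut
toyProfiles <- function(m, groups = rep("g", ncol(m)), scale = "log2") {
    if (is.null(rownames(m))) rownames(m) <- sprintf("m%02d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    MetaboliteProfiles(m, groups = groups, scale = scale)
}
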