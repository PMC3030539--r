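# DPClus-style density / cluster-property graph clustering.
#
# Working representation: adjacency as a named list of sorted character
# vectors. All orderings are total (weight, degree, lexicographic id) so
# identical input yields identical output.

.adjList <- function(graph) {
    if (is.null(igraph::V(graph)$name))
        igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
    nodes <- sort(igraph::V(graph)$name)
    el <- igraph::as_edgelist(graph)
    adj <- stats::setNames(vector("list", length(nodes)), nodes)
    for (v in nodes) adj[[v]] <- character(0)
    if (nrow(el)) {
        for (k in seq_len(nrow(el))) {
            u <- el[k, 1]; v <- el[k, 2]
            if (u == v) next
            adj[[u]] <- c(adj[[u]], v)
            adj[[v]] <- c(adj[[v]], u)
        }
        adj <- lapply(adj, function(x) sort(unique(x)))
    }
    adj
}

.edgeCount <- function(adj) sum(lengths(adj)) / 2

#' Common-neighbor edge weights and node weights
#'
#' The weight of an edge (u, v) is the number of neighbors u and v share;
#' the weight of a node is the sum of its incident edge weights. Dense
#' neighborhoods concentrate weight, so the heaviest node seeds cluster
#' growth.
#'
#' @param graph an undirected simple igraph.
#' @return list with \code{edges} (data.frame u, v, weight; u < v) and
#'   \code{nodes} (named numeric vector).
#' @export
edgeNodeWeights <- function(graph) {
    adj <- .adjList(graph)
    .edgeNodeWeightsAdj(adj)
}

.edgeNodeWeightsAdj <- function(adj) {
    nodes <- names(adj)
    W <- stats::setNames(numeric(length(nodes)), nodes)
    us <- character(0); vs <- character(0); ws <- numeric(0)
    for (u in nodes) {
        for (v in adj[[u]]) {
            if (u < v) {
                w <- length(intersect(adj[[u]], adj[[v]]))
                us <- c(us, u); vs <- c(vs, v); ws <- c(ws, w)
                W[u] <- W[u] + w
                W[v] <- W[v] + w
            }
        }
    }
    list(edges = data.frame(u = us, v = vs, weight = ws,
                            stringsAsFactors = FALSE),
         nodes = W)
}

.clusterDensity <- function(members, adj) {
    k <- length(members)
    if (k < 2) return(1)  # singleton: defined as 1 so growth can start
    e <- sum(vapply(members,
                    function(v) sum(adj[[v]] %in% members), numeric(1))) / 2
    2 * e / (k * (k - 1))
}

#' Cluster property of a candidate node
#'
#' For a node n outside cluster k: \eqn{cp_{nk} = E_{nk} / (d_k |N_k|)}
#' where \eqn{E_{nk}} counts edges from n into the cluster and \eqn{d_k}
#' is the cluster density. Measures how strongly the periphery node is
#' tied to the cluster relative to the cluster's own connectivity.
#'
#' @param node node id (must not belong to the cluster).
#' @param cluster character vector of member ids.
#' @param graph the igraph the cluster lives in.
#' @return cp value; NA when the cluster density is 0 (candidate rejected).
#' @export
clusterProperty <- function(node, cluster, graph) {
    adj <- .adjList(graph)
    stopIfNot(!(node %in% cluster), "node must lie outside the cluster")
    d <- .clusterDensity(cluster, adj)
    if (d == 0) return(NA_real_)
    sum(adj[[node]] %in% cluster) / (d * length(cluster))
}

# Order candidate ids by (edges-into-cluster desc, node weight desc, id asc).
.orderCandidates <- function(cand, eIn, W) {
    cand[order(-eIn, -W[cand], cand, method = "radix")]
}

# Grow a cluster from `members` inside adjacency `adj`, adding at each pass
# the first candidate (in the total order) whose addition keeps density
# >= dIn and whose cp >= cpIn. Returns the grown member vector.
.growCluster <- function(members, adj, W, cpIn, dIn) {
    eInside <- 0
    k <- length(members)
    if (k > 1) eInside <- .clusterDensity(members, adj) * k * (k - 1) / 2
    repeat {
        k <- length(members)
        dK <- if (k < 2) 1 else 2 * eInside / (k * (k - 1))
        cand <- setdiff(sort(unique(unlist(adj[members], use.names = FALSE))),
                        members)
        if (!length(cand)) break
        eIn <- vapply(cand, function(n) sum(adj[[n]] %in% members), numeric(1))
        cand <- .orderCandidates(cand, eIn, W)
        eIn <- vapply(cand, function(n) sum(adj[[n]] %in% members), numeric(1))
        added <- FALSE
        for (i in seq_along(cand)) {
            newDens <- 2 * (eInside + eIn[i]) / ((k + 1) * k)
            cp <- eIn[i] / (dK * k)
            if (newDens >= dIn && cp >= cpIn) {
                members <- c(members, cand[i])
                eInside <- eInside + eIn[i]
                added <- TRUE
                break
            }
        }
        if (!added) break
    }
    sort(members)
}

#' DPClus graph clustering
#'
#' Iteratively extracts densely connected clusters: compute common-neighbor
#' edge/node weights on the working graph, seed a cluster at the heaviest
#' node (ties: higher degree, then lexicographic id), grow it while the
#' density stays >= \code{dIn} and each joining node's cluster property is
#' >= \code{cpIn}, emit it (if at least \code{minClusterSize} nodes),
#' remove its nodes from the working graph, and repeat until no edges
#' remain. In overlapping mode each emitted cluster is additionally
#' extended in the original graph by previously-removed neighbors that
#' still meet the cp and density conditions; the extension never alters
#' the working graph, so clusters may share metabolites, as metabolic
#' pathways do.
#'
#' @param graph an undirected simple igraph.
#' @param params a \code{\link{DPClusParams}} object.
#' @return A \linkS4class{DPClusResult}; clusters are in extraction order,
#'   each with its density measured in the original graph.
#' @export
runDPClus <- function(graph, params = DPClusParams()) {
    adjOrig <- .adjList(graph)
    wOrig <- .edgeNodeWeightsAdj(adjOrig)$nodes
    adj <- adjOrig
    clusters <- list()
    clustered <- character(0)

    while (.edgeCount(adj) > 0) {
        ww <- .edgeNodeWeightsAdj(adj)$nodes
        deg <- lengths(adj)
        nodes <- names(adj)
        seedNode <- nodes[order(-ww, -deg, nodes, method = "radix")][1]

        members <- .growCluster(seedNode, adj, ww, params@cpIn, params@dIn)

        extended <- character(0)
        if (length(members) >= params@minClusterSize) {
            full <- members
            if (params@overlapping) {
                grown <- .growClusterExt(members, adjOrig, wOrig,
                                         params@cpIn, params@dIn)
                extended <- setdiff(grown, members)
                full <- grown
            }
            clusters[[length(clusters) + 1L]] <- list(
                members = sort(full),
                density = .clusterDensity(sort(full), adjOrig),
                seedNode = seedNode,
                extendedMembers = sort(extended))
            clustered <- union(clustered, full)
        }
        # remove grown members (not extension) from the working graph
        adj <- adj[!(names(adj) %in% members)]
        adj <- lapply(adj, function(x) x[!(x %in% members)])
    }
    new("DPClusResult", clusters = clusters,
        unclustered = setdiff(sort(names(adjOrig)), clustered),
        params = params)
}

# Overlapping extension: same growth rule, but candidates are drawn from
# (and evaluated in) the original graph.
.growClusterExt <- function(members, adjOrig, wOrig, cpIn, dIn) {
    .growCluster(members, adjOrig, wOrig, cpIn, dIn)
}

#' Cluster-level adjacency graph
#'
#' Nodes are clusters; two clusters are connected iff they share a member
#' (overlapping mode) or at least one original edge runs between them.
#'
#' @param result a \linkS4class{DPClusResult}.
#' @param graph the original igraph.
#' @return An igraph whose vertices are \code{cluster1, cluster2, ...} with
#'   vertex attribute \code{size}.
#' @export
clusterAdjacency <- function(result, graph) {
    mem <- clusterMembers(result)
    nC <- length(mem)
    adj <- .adjList(graph)
    ids <- sprintf("cluster%d", seq_len(nC))
    edges <- character(0)
    if (nC >= 2) {
        for (i in seq_len(nC - 1)) {
            for (j in (i + 1):nC) {
                shared <- length(intersect(mem[[i]], mem[[j]])) > 0
                crossEdge <- any(vapply(mem[[i]], function(v)
                    any(adj[[v]] %in% mem[[j]]), logical(1)))
                if (shared || crossEdge)
                    edges <- c(edges, ids[i], ids[j])
            }
        }
    }
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nC, name = ids, size = lengths(mem))
    if (length(edges)) g <- igraph::add_edges(g, match(edges, ids))
    g
}
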