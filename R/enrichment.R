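#' Pathway over-representation of one cluster (Fisher's exact test)
#'
#' For each pathway, builds the 2x2 contingency table over the annotation
#' universe (cluster and pathway both restricted to it) and computes the
#' one-sided over-representation p-value, the upper hypergeometric tail
#' \eqn{P(X \ge a)} with pathway size a+b, cluster size a+c and universe
#' size n. Significance is declared at p <= 0.05. No multiple-testing
#' correction is applied across pathways: the cluster-set S-value
#' permutation null is the global control.
#'
#' @param cluster character vector of cluster member ids (or a single
#'   cluster entry from \code{\link{runDPClus}} via
#'   \code{clusterMembers()}).
#' @param annotation a \linkS4class{PathwayAnnotation}, typically already
#'   restricted to the analyzed metabolites with
#'   \code{\link{restrictUniverse}}.
#' @return list: \code{table} (data.frame pathway, a, b, c, d, p),
#'   \code{pMin}, \code{bestPathway}, \code{significant}. A cluster with no
#'   member in the universe yields \code{pMin = NA} ("n.s.") with a
#'   message.
#' @export
fisherExactEnrichment <- function(cluster, annotation) {
    universe <- annotationUniverse(annotation)
    n <- length(universe)
    cl <- intersect(unique(cluster), universe)
    members <- pathwayMembers(annotation)
    if (length(cl) == 0) {
        message("cluster has no member in the annotation universe: n.s.")
        return(list(table = data.frame(pathway = character(0), a = integer(0),
                                       b = integer(0), c = integer(0),
                                       d = integer(0), p = numeric(0)),
                    pMin = NA_real_, bestPathway = NA_character_,
                    significant = NA))
    }
    a <- vapply(members, function(pw) length(intersect(pw, cl)), integer(1))
    K <- lengths(members)                       # pathway sizes (a + b)
    k <- length(cl)                             # cluster size (a + c)
    p <- stats::phyper(a - 1L, K, n - K, k, lower.tail = FALSE)
    tab <- data.frame(pathway = names(members), a = a, b = K - a,
                      c = k - a, d = n - K - k + a, p = p, row.names = NULL)
    best <- which.min(tab$p)
    list(table = tab, pMin = tab$p[best], bestPathway = tab$pathway[best],
         significant = tab$p[best] <= 0.05)
}

#' S-value of a cluster set
#'
#' The mean over clusters of each cluster's best (minimum) pathway
#' enrichment p-value. Clusters with undefined \eqn{p_{min}} (no annotated
#' member) are excluded with a warning; all-undefined is an error.
#'
#' @param pMins numeric vector of per-cluster minimum p-values.
#' @return the S-value in [0, 1].
#' @export
sValue <- function(pMins) {
    stopIfNot(length(pMins) > 0, "no clusters supplied")
    if (anyNA(pMins)) {
        stopIfNot(!all(is.na(pMins)), "no cluster has a defined p_min")
        warning(sprintf("%d cluster(s) without defined p_min excluded from S",
                        sum(is.na(pMins))))
    }
    mean(pMins, na.rm = TRUE)
}

#' Size-preserving randomized cluster sets
#'
#' Each randomized set replaces every cluster's members with a uniform
#' random draw (without replacement within a cluster) from the universe,
#' preserving each cluster's size; draws are independent across clusters
#' and sets. With \code{globalPermutation = TRUE} one random relabeling of
#' the universe is applied per set instead (a strict permutation of the
#' metabolite names, preserving any overlap structure).
#'
#' @param clusters list of member vectors (e.g.
#'   \code{clusterMembers(result)}).
#' @param universe character vector to draw from.
#' @param nRandom number of randomized sets (default 100).
#' @param seed integer seed.
#' @param globalPermutation use one universe-wide permutation per set.
#' @return list of \code{nRandom} lists of member vectors.
#' @export
randomizedClusterSets <- function(clusters, universe, nRandom = 100L, seed,
                                  globalPermutation = FALSE) {
    stopIfNot(nRandom >= 1, "nRandom must be >= 1")
    stopIfNot(!missing(seed), "'seed' is required")
    sizes <- lengths(clusters)
    stopIfNot(all(sizes <= length(universe)),
              "a cluster is larger than the universe")
    withSeed(as.integer(seed), {
        lapply(seq_len(nRandom), function(s) {
            if (globalPermutation) {
                relabel <- stats::setNames(sample(universe), universe)
                lapply(clusters, function(cl)
                    unname(relabel[intersect(cl, universe)]))
            } else {
                lapply(sizes, function(k) sample(universe, k))
            }
        })
    })
}

#' Assess a cluster set against a permutation null (S-value)
#'
#' Computes per-cluster pathway enrichment, the real S-value, and the null
#' S distribution over size-preserving randomized cluster sets; the
#' empirical p-value is \eqn{(1 + \#\{null\ S \le S\}) / (nRandom + 1)}
#' (never exactly 0).
#'
#' @param clusters list of member vectors, or a
#'   \linkS4class{DPClusResult}.
#' @param annotation a \linkS4class{PathwayAnnotation} restricted to the
#'   analyzed metabolites.
#' @param nRandom number of randomized cluster sets (default 100).
#' @param seed integer seed.
#' @param globalPermutation see \code{\link{randomizedClusterSets}}.
#' @return A \linkS4class{ClusterAssessment}.
#' @export
assessClusters <- function(clusters, annotation, nRandom = 100L, seed,
                           globalPermutation = FALSE) {
    if (is(clusters, "DPClusResult")) clusters <- clusterMembers(clusters)
    stopIfNot(length(clusters) > 0, "no clusters to assess")
    enr <- lapply(clusters, fisherExactEnrichment, annotation = annotation)
    pMins <- vapply(enr, `[[`, numeric(1), "pMin")
    S <- sValue(pMins)
    universe <- annotationUniverse(annotation)
    sets <- randomizedClusterSets(clusters, universe, nRandom = nRandom,
                                  seed = seed,
                                  globalPermutation = globalPermutation)
    nullS <- vapply(sets, function(set) {
        pm <- vapply(set, function(cl)
            fisherExactEnrichment(cl, annotation)$pMin, numeric(1))
        mean(pm, na.rm = TRUE)
    }, numeric(1))
    empP <- (1 + sum(nullS <= S)) / (nRandom + 1)
    perCluster <- data.frame(
        cluster = seq_along(clusters),
        size = lengths(clusters),
        pMin = pMins,
        bestPathway = vapply(enr, `[[`, character(1), "bestPathway"))
    new("ClusterAssessment", S = S, nullS = nullS,
        nRandom = as.integer(nRandom), empiricalP = empP,
        perCluster = perCluster)
}
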