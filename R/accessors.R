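#' Accessors for MetaboliteProfiles
#'
#' @param x a \linkS4class{MetaboliteProfiles} object.
#' @return \code{profileValues}: the abundance matrix;
#'   \code{sampleGroups}/\code{sampleTissue}: named character vectors;
#'   \code{profileScale}: \code{"raw"} or \code{"log2"}.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
profileValues <- function(x) assay(x, "abundance")

#' @rdname profile-accessors
#' @export
sampleGroups <- function(x) {
    g <- colData(x)$group
    names(g) <- colnames(x)
    g
}

#' @rdname profile-accessors
#' @export
sampleTissue <- function(x) {
    t <- colData(x)$tissue
    names(t) <- colnames(x)
    t
}

#' @rdname profile-accessors
#' @export
profileScale <- function(x) metadata(x)$scale

#' Accessors for PathwayAnnotation
#'
#' @param x a \linkS4class{PathwayAnnotation}.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
pathwayIds <- function(x) names(x@members)

#' @rdname annotation-accessors
#' @export
pathwayMembers <- function(x) x@members

#' @rdname annotation-accessors
#' @export
annotationUniverse <- function(x) x@universe

#' Restrict an annotation to a set of analyzed metabolites
#'
#' Intersects the universe and every pathway with \code{metabolites};
#' pathways emptied by the restriction are dropped with a warning.
#'
#' @param x a \linkS4class{PathwayAnnotation}.
#' @param metabolites character vector of metabolite ids.
#' @return A restricted \linkS4class{PathwayAnnotation}.
#' @export
restrictUniverse <- function(x, metabolites) {
    PathwayAnnotation(pathwayMembers(x),
                      universe = intersect(annotationUniverse(x), metabolites))
}

#' Accessors for DPClusResult
#'
#' @param x a \linkS4class{DPClusResult}.
#' @name dpclus-accessors
NULL

#' @rdname dpclus-accessors
#' @export
clusterMembers <- function(x) lapply(x@clusters, `[[`, "members")

#' @rdname dpclus-accessors
#' @export
clusterDensities <- function(x) vapply(x@clusters, `[[`, numeric(1), "density")

#' @rdname dpclus-accessors
#' @export
unclusteredNodes <- function(x) x@unclustered

#' @rdname dpclus-accessors
#' @export
nClusters <- function(x) length(x@clusters)

#' Accessors for ClusterAssessment
#'
#' @param x a \linkS4class{ClusterAssessment}.
#' @name assessment-accessors
NULL

#' @rdname assessment-accessors
#' @export
sValueOf <- function(x) x@S

#' @rdname assessment-accessors
#' @export
nullSValues <- function(x) x@nullS

#' @rdname assessment-accessors
#' @export
empiricalP <- function(x) x@empiricalP

#' @rdname assessment-accessors
#' @export
perClusterEnrichment <- function(x) x@perCluster

setMethod("show", "MetaboliteProfiles", function(object) {
    cat(sprintf("MetaboliteProfiles: %d metabolites x %d samples (%s scale)\n",
                nrow(object), ncol(object), profileScale(object)))
    tab <- table(colData(object)$group)
    cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
})

setMethod("show", "PathwayAnnotation", function(object) {
    cat(sprintf("PathwayAnnotation: %d pathways over a universe of %d metabolites\n",
                length(object@members), length(object@universe)))
    if (length(object@members))
        cat("  sizes:", paste(range(lengths(object@members)), collapse = "-"),
            "(min-max)\n")
})

setMethod("show", "DPClusParams", function(object) {
    cat(sprintf("DPClusParams: cp >= %g, density >= %g, overlapping = %s, min size = %d\n",
                object@cpIn, object@dIn, object@overlapping,
                object@minClusterSize))
})

setMethod("show", "DPClusResult", function(object) {
    sz <- lengths(clusterMembers(object))
    cat(sprintf("DPClusResult: %d cluster(s)%s; %d unclustered node(s)\n",
                length(sz),
                if (length(sz)) sprintf(" of sizes %s", paste(sz, collapse = ", "))
                else "",
                length(object@unclustered)))
})

setMethod("show", "ClusterAssessment", function(object) {
    cat(sprintf("ClusterAssessment: S = %.4g over %d cluster(s); empirical p = %.4g (%d randomized sets)\n",
                object@S, nrow(object@perCluster), object@empiricalP,
                object@nRandom))
})
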