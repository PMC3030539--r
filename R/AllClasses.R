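#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Container for metabolite profile matrices
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a
#' metabolites x samples matrix of relative abundances together with the
#' sample metadata the pipeline needs (a \code{group} label per sample and
#' an optional \code{tissue} label). The assay is named \code{"abundance"}.
#' \code{metadata(x)$scale} records whether values are \code{"raw"}
#' (relative abundances, all positive) or \code{"log2"} (after
#' \code{\link{log2Transform}}).
#'
#' @slot .
#' @seealso \code{\link{MetaboliteProfiles}} for the constructor.
#' @export
setClass("MetaboliteProfiles", contains = "SummarizedExperiment")

setValidity("MetaboliteProfiles", function(object) {
    msg <- character()
    rn <- rownames(object)
    cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, sprintf("duplicate or missing metabolite ids: %s",
                 paste(unique(rn[duplicated(rn)]), collapse = ", ")))
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, sprintf("duplicate or missing sample ids: %s",
                 paste(unique(cn[duplicated(cn)]), collapse = ", ")))
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    sc <- metadata(object)$scale
    if (is.null(sc) || !sc %in% c("raw", "log2"))
        msg <- c(msg, "metadata(object)$scale must be 'raw' or 'log2'")
    if (length(msg)) msg else TRUE
})

#' Construct a MetaboliteProfiles object
#'
#' @param values numeric matrix, metabolites in rows (unique rownames),
#'   samples in columns (unique colnames). Missing values are allowed and
#'   encoded as \code{NA}.
#' @param groups character vector of group labels, one per sample (recycled
#'   names are matched to \code{colnames(values)} when named).
#' @param tissue optional character vector of tissue labels per sample.
#' @param scale either \code{"raw"} (positive relative abundances) or
#'   \code{"log2"}.
#' @return A \linkS4class{MetaboliteProfiles} object.
#' @examples
#' m <- matrix(2^rnorm(12, 10), 3, 4,
#'             dimnames = list(paste0("met", 1:3), paste0("s", 1:4)))
#' mp <- MetaboliteProfiles(m, groups = rep(c("WT", "mto1"), each = 2))
#' @export
MetaboliteProfiles <- function(values, groups, tissue = NULL,
                               scale = c("raw", "log2")) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (length(groups) != ncol(values))
        stop("'groups' must have one label per sample")
    cd <- DataFrame(group = as.character(groups),
                    row.names = colnames(values))
    cd$tissue <- if (is.null(tissue)) NA_character_ else as.character(tissue)
    se <- SummarizedExperiment(assays = list(abundance = values),
                               colData = cd)
    metadata(se)$scale <- scale
    new("MetaboliteProfiles", se)
}

#' Pathway annotation: named metabolite sets over a universe
#'
#' @slot members named list; each element is a character vector of
#'   metabolite ids belonging to that pathway.
#' @slot universe character vector of metabolite ids eligible for testing.
#' @export
setClass("PathwayAnnotation",
         representation(members = "list", universe = "character"))

setValidity("PathwayAnnotation", function(object) {
    msg <- character()
    if (length(object@members)) {
        if (is.null(names(object@members)) ||
            anyDuplicated(names(object@members)))
            msg <- c(msg, "pathway ids must be unique and non-empty")
        if (!all(unlist(object@members) %in% object@universe))
            msg <- c(msg, "all pathway members must lie in the universe")
        if (any(lengths(object@members) == 0))
            msg <- c(msg, "empty pathways are not allowed (drop them)")
    }
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe contains duplicate ids")
    if (length(msg)) msg else TRUE
})

#' Construct a PathwayAnnotation
#'
#' Empty pathways are dropped with a warning. The universe defaults to the
#' union of all members.
#'
#' @param members named list of character vectors (pathway id -> members).
#' @param universe optional character vector; defaults to the union of
#'   members. Members outside a supplied universe are removed.
#' @return A \linkS4class{PathwayAnnotation}.
#' @export
PathwayAnnotation <- function(members, universe = NULL) {
    members <- lapply(members, function(m) unique(as.character(m)))
    if (is.null(universe)) {
        universe <- sort(unique(unlist(members, use.names = FALSE)))
    } else {
        universe <- sort(unique(as.character(universe)))
        members <- lapply(members, function(m) m[m %in% universe])
    }
    empty <- lengths(members) == 0
    if (any(empty)) {
        warning(sprintf("dropping %d empty pathway(s): %s", sum(empty),
                        paste(names(members)[empty], collapse = ", ")))
        members <- members[!empty]
    }
    new("PathwayAnnotation", members = members, universe = universe)
}

#' Parameters for DPClus graph clustering
#'
#' Defaults follow the analysis the package reproduces: both the minimum
#' cluster property \code{cpIn} and the minimum density \code{dIn} are 0.5
#' and the overlapping mode is on.
#'
#' @slot cpIn minimum cluster property, in (0, 1].
#' @slot dIn minimum cluster density, in (0, 1].
#' @slot overlapping logical; extend emitted clusters in the original graph.
#' @slot minClusterSize smallest cluster reported.
#' @export
setClass("DPClusParams",
         representation(cpIn = "numeric", dIn = "numeric",
                        overlapping = "logical", minClusterSize = "integer"),
         prototype(cpIn = 0.5, dIn = 0.5, overlapping = TRUE,
                   minClusterSize = 2L))

setValidity("DPClusParams", function(object) {
    msg <- character()
    if (object@cpIn <= 0 || object@cpIn > 1) msg <- c(msg, "cpIn must be in (0,1]")
    if (object@dIn <= 0 || object@dIn > 1) msg <- c(msg, "dIn must be in (0,1]")
    if (object@minClusterSize < 1L) msg <- c(msg, "minClusterSize must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname DPClusParams-class
#' @param cpIn,dIn,overlapping,minClusterSize see slots.
#' @export
DPClusParams <- function(cpIn = 0.5, dIn = 0.5, overlapping = TRUE,
                         minClusterSize = 2L) {
    new("DPClusParams", cpIn = cpIn, dIn = dIn, overlapping = overlapping,
        minClusterSize = as.integer(minClusterSize))
}

#' Result of DPClus clustering
#'
#' @slot clusters list; each element has \code{members}, \code{density}
#'   (within the original graph), \code{seedNode} and
#'   \code{extendedMembers} (members added by the overlapping extension).
#' @slot unclustered character; nodes in no emitted cluster.
#' @slot params the \linkS4class{DPClusParams} used.
#' @export
setClass("DPClusResult",
         representation(clusters = "list", unclustered = "character",
                        params = "DPClusParams"))

#' Cluster-set assessment against a permutation null
#'
#' Holds the S-value (mean over clusters of the best pathway-enrichment
#' p-value), the null S distribution from size-preserving randomized
#' cluster sets, and the empirical p-value.
#'
#' @slot S numeric; mean of per-cluster minimum enrichment p-values.
#' @slot nullS numeric vector of null S values.
#' @slot nRandom number of randomized cluster sets.
#' @slot empiricalP (1 + #\{null S <= S\}) / (nRandom + 1).
#' @slot perCluster data.frame: cluster, size, pMin, bestPathway.
#' @export
setClass("ClusterAssessment",
         representation(S = "numeric", nullS = "numeric", nRandom = "integer",
                        empiricalP = "numeric", perCluster = "data.frame"))
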