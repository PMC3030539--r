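#' Read a metabolite profile matrix with sample metadata
#'
#' The matrix file is TSV or CSV (by extension, \code{.csv} = comma) with a
#' header row of sample ids and metabolite ids in the first column. The
#' metadata file maps every sample id to a group (columns \code{sample},
#' \code{group}, optional \code{tissue}). Unparseable numeric cells become
#' missing values with the count reported via \code{message()}.
#'
#' @param path matrix file.
#' @param metadataPath sample metadata file.
#' @param scale \code{"raw"} or \code{"log2"}; how the stored values are to
#'   be interpreted.
#' @return A \linkS4class{MetaboliteProfiles}.
#' @export
readProfileMatrix <- function(path, metadataPath, scale = c("raw", "log2")) {
    scale <- match.arg(scale)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             quote = "", comment.char = "")
    stopIfNot(ncol(raw) >= 2, "matrix file needs an id column plus samples")
    ids <- raw[[1]]
    dup <- unique(ids[duplicated(ids)])
    stopIfNot(length(dup) == 0, "duplicated metabolite id(s): %s",
              paste(dup, collapse = ", "))
    m <- suppressWarnings(
        vapply(raw[-1], as.numeric, numeric(nrow(raw))))
    m <- matrix(m, nrow = nrow(raw),
                dimnames = list(ids, colnames(raw)[-1]))
    nBad <- sum(is.na(m) & !(toupper(trimws(as.matrix(raw[-1]))) %in%
                             c("NA", "", "NAN")))
    nMissing <- sum(is.na(m))
    if (nMissing)
        message(sprintf("%d missing value(s) (%d from unparseable cells)",
                        nMissing, nBad))
    dupS <- unique(colnames(m)[duplicated(colnames(m))])
    stopIfNot(length(dupS) == 0, "duplicated sample id(s): %s",
              paste(dupS, collapse = ", "))

    md <- utils::read.table(metadataPath, sep = sep, header = TRUE,
                            colClasses = "character", check.names = FALSE)
    stopIfNot(all(c("sample", "group") %in% colnames(md)),
              "metadata needs 'sample' and 'group' columns")
    absent <- setdiff(colnames(m), md$sample)
    stopIfNot(length(absent) == 0,
              "sample(s) in matrix absent from metadata: %s",
              paste(absent, collapse = ", "))
    md <- md[match(colnames(m), md$sample), ]
    MetaboliteProfiles(m, groups = md$group,
                       tissue = if ("tissue" %in% colnames(md)) md$tissue else NULL,
                       scale = scale)
}

#' Write a profile matrix and its sample metadata as TSV
#'
#' Deterministic: preserves row/column order; repeated runs are
#' byte-identical.
#'
#' @param x a \linkS4class{MetaboliteProfiles}.
#' @param path matrix TSV (first column \code{metabolite}).
#' @param metadataPath metadata TSV (\code{sample}, \code{group},
#'   \code{tissue}).
#' @export
writeProfileMatrix <- function(x, path, metadataPath) {
    m <- profileValues(x)
    df <- data.frame(metabolite = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    md <- data.frame(sample = colnames(m),
                     group = unname(sampleGroups(x)),
                     tissue = unname(sampleTissue(x)))
    utils::write.table(md, metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(NULL)
}

#' Read a pathway annotation (two-column TSV or GMT)
#'
#' Two-column format: \code{metabolite <tab> pathway} per line (header
#' optional, detected when the first line repeats the column names
#' \code{metabolite}/\code{pathway}). GMT format (\code{.gmt}):
#' \code{pathway <tab> description <tab> member...}. Pathways with no
#' parsed members are dropped with a warning; an annotation with no
#' pathways at all is an error.
#'
#' @param path annotation file.
#' @return A \linkS4class{PathwayAnnotation}; the universe is the union of
#'   all members (restrict later with \code{\link{restrictUniverse}}).
#' @export
readAnnotation <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    stopIfNot(length(lines) > 0, "annotation file is empty: %s", path)
    if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
        fields <- strsplit(lines, "\t", fixed = TRUE)
        members <- lapply(fields, function(f)
            unique(f[-(1:2)][nzchar(f[-(1:2)])]))
        names(members) <- vapply(fields, `[[`, character(1), 1L)
    } else {
        fields <- strsplit(lines, "\t", fixed = TRUE)
        stopIfNot(all(lengths(fields) >= 2),
                  "two-column annotation: every line needs metabolite<TAB>pathway")
        df <- data.frame(metabolite = vapply(fields, `[[`, character(1), 1L),
                         pathway = vapply(fields, `[[`, character(1), 2L))
        if (tolower(df$metabolite[1]) == "metabolite" &&
            tolower(df$pathway[1]) == "pathway")
            df <- df[-1, , drop = FALSE]
        stopIfNot(nrow(df) > 0, "annotation file has no entries: %s", path)
        members <- split(df$metabolite, df$pathway)
        members <- lapply(members, unique)
    }
    stopIfNot(length(members) > 0, "annotation file has no pathways: %s", path)
    PathwayAnnotation(members)
}

#' Write a pathway annotation
#'
#' @param x a \linkS4class{PathwayAnnotation}.
#' @param path output file; \code{.gmt} writes GMT, anything else the
#'   two-column \code{metabolite <tab> pathway} TSV (sorted, byte-stable).
#' @export
writeAnnotation <- function(x, path) {
    members <- pathwayMembers(x)
    if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
        lines <- vapply(sort(names(members)), function(p)
            paste(c(p, p, sort(members[[p]])), collapse = "\t"), character(1))
        writeLines(lines, path)
    } else {
        df <- data.frame(
            metabolite = unlist(members, use.names = FALSE),
            pathway = rep(names(members), lengths(members)))
        df <- df[order(df$metabolite, df$pathway), ]
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
    }
    invisible(NULL)
}

#' Write a correlation network
#'
#' Edge-list TSV has columns \code{source}, \code{target}, \code{r}, with
#' \code{source < target} per row and rows sorted lexicographically for
#' byte-stable output. GraphML (via igraph) carries \code{r} as an edge
#' attribute.
#'
#' @param graph an igraph network from \code{\link{buildNetwork}}.
#' @param path output file.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @export
writeNetwork <- function(graph, path, format = c("edgelist", "graphml")) {
    format <- match.arg(format)
    if (format == "graphml") {
        igraph::write_graph(graph, path, format = "graphml")
        return(invisible(NULL))
    }
    el <- igraph::as_edgelist(graph)
    r <- igraph::edge_attr(graph, "r")
    if (nrow(el)) {
        swap <- el[, 1] > el[, 2]
        el[swap, ] <- el[swap, 2:1]
        o <- order(el[, 1], el[, 2])
        df <- data.frame(source = el[o, 1], target = el[o, 2],
                         r = if (is.null(r)) NA_real_ else r[o])
    } else {
        df <- data.frame(source = character(0), target = character(0),
                         r = numeric(0))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' Read a network written by \code{\link{writeNetwork}}
#'
#' @param path input file.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @return An undirected igraph with edge attribute \code{r}.
#' @export
readNetwork <- function(path, format = c("edgelist", "graphml")) {
    format <- match.arg(format)
    if (format == "graphml")
        return(igraph::read_graph(path, format = "graphml"))
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character", "numeric"))
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
    g
}

#' Write DPClus clusters as JSON
#'
#' @param x a \linkS4class{DPClusResult}.
#' @param path output JSON file.
#' @export
writeClusters <- function(x, path) {
    cl <- lapply(seq_along(x@clusters), function(i) {
        c0 <- x@clusters[[i]]
        list(cluster = i, seed = c0$seedNode, density = c0$density,
             members = c0$members, extended = c0$extendedMembers)
    })
    jsonlite::write_json(list(clusters = cl, unclustered = x@unclustered,
                              params = list(cp = x@params@cpIn,
                                            density = x@params@dIn,
                                            overlapping = x@params@overlapping,
                                            min_size = x@params@minClusterSize)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(NULL)
}
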