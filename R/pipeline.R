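#' Run the full correlation-network analysis pipeline
#'
#' Orchestrates, per sample group: log2 transform (when raw), rank-product
#' differential abundance against a reference group, PCA over all samples,
#' Spearman correlations with local-fdr edge calls, a threshold sweep
#' against randomized-data nulls with automatic threshold selection,
#' network construction, DPClus clustering, and (when an annotation is
#' supplied) pathway enrichment with the S-value permutation assessment.
#' Differential correlations (Fisher Z + local fdr) are computed for every
#' pair of groups. All stage seeds derive deterministically from
#' \code{seed}, so identical config + seed reproduces an identical bundle.
#'
#' @param profiles a \linkS4class{MetaboliteProfiles}.
#' @param annotation optional \linkS4class{PathwayAnnotation}.
#' @param referenceGroup group label used as rank-product reference
#'   (default: first group).
#' @param fdrCutoff significance level on local fdr (default 0.05).
#' @param thresholdOverride if non-NULL, skip automatic selection and use
#'   this correlation threshold (the canonical analysis uses 0.5).
#' @param gridStep sweep grid spacing (default 0.01).
#' @param nRandom randomized datasets for the sweep null and randomized
#'   cluster sets for the S assessment (default 100).
#' @param nPerm rank-product permutations (default 1000).
#' @param dpclusParams a \code{\link{DPClusParams}}.
#' @param seed integer master seed (required).
#' @param outDir optional directory; when given, every artifact is written
#'   (TSV tables, GraphML networks, cluster/assessment JSON, resolved
#'   config and run log).
#' @return A list of class \code{"PipelineBundle"}: \code{profiles} (log2),
#'   \code{rankProduct}, \code{pca}, and per group under \code{groups}:
#'   \code{correlations}, \code{nSignificantEdges}, \code{sweep},
#'   \code{threshold}, \code{network}, \code{clusters}, \code{enrichment},
#'   \code{assessment}; plus \code{differential} (per group pair) and
#'   \code{summary} (edge/differential counts).
#' @export
runPipeline <- function(profiles, annotation = NULL, referenceGroup = NULL,
                        fdrCutoff = 0.05, thresholdOverride = NULL,
                        gridStep = 0.01, nRandom = 100L, nPerm = 1000L,
                        dpclusParams = DPClusParams(), seed, outDir = NULL) {
    stopIfNot(!missing(seed), "'seed' is required")
    seed <- as.integer(seed)
    if (profileScale(profiles) == "raw") profiles <- log2Transform(profiles)
    groups <- unique(unname(sampleGroups(profiles)))
    if (is.null(referenceGroup)) referenceGroup <- groups[1]
    stopIfNot(referenceGroup %in% groups, "unknown reference group '%s'",
              referenceGroup)

    rp <- NULL
    others <- setdiff(groups, referenceGroup)
    if (length(others) && !anyNA(profileValues(profiles))) {
        rp <- do.call(rbind, lapply(others, function(g) {
            r <- rankProductTest(profiles, g, referenceGroup, nPerm = nPerm,
                                 seed = childSeed(seed, paste0("rankprod_", g)))
            cbind(contrast = sprintf("%s_vs_%s", g, referenceGroup), r)
        }))
    }
    pca <- pcaProfiles(profiles)

    ann <- annotation
    if (!is.null(ann))
        ann <- restrictUniverse(ann, rownames(profiles))

    perGroup <- lapply(groups, function(g) {
        idx <- which(unname(sampleGroups(profiles)) == g)
        ct <- suppressWarnings(spearmanCorrelations(profiles,
                                                    sampleSubset = idx))
        ct$fdr <- localFdr(ct$p)
        nSig <- sum(ct$fdr < fdrCutoff & !is.na(ct$fdr) & ct$r > 0)
        nulls <- randomizeProfiles(profiles[, idx], nRandom = nRandom,
                                   seed = childSeed(seed, paste0("null_", g)))
        sweep <- sweepThresholds(ct, nullMatrices = nulls,
                                 gridStep = gridStep)
        th <- selectThreshold(sweep, override = thresholdOverride)
        net <- buildNetwork(ct, threshold = th)
        cl <- runDPClus(net, dpclusParams)
        enr <- assess <- NULL
        if (!is.null(ann) && nClusters(cl) > 0) {
            enr <- lapply(clusterMembers(cl), fisherExactEnrichment,
                          annotation = ann)
            assess <- assessClusters(cl, ann, nRandom = nRandom,
                                     seed = childSeed(seed, paste0("assess_", g)))
        }
        list(group = g, correlations = ct, nSignificantEdges = nSig,
             sweep = sweep, threshold = th, network = net, clusters = cl,
             enrichment = enr, assessment = assess)
    })
    names(perGroup) <- groups

    differential <- list()
    if (length(groups) >= 2) {
        cmb <- utils::combn(groups, 2)
        for (k in seq_len(ncol(cmb))) {
            g1 <- cmb[1, k]; g2 <- cmb[2, k]
            dc <- differentialCorrelations(perGroup[[g1]]$correlations,
                                           perGroup[[g2]]$correlations)
            differential[[sprintf("%s_vs_%s", g1, g2)]] <- dc
        }
    }

    summary <- data.frame(
        group = groups,
        nSamples = as.integer(table(sampleGroups(profiles))[groups]),
        nSignificantEdges = vapply(perGroup, `[[`, numeric(1),
                                   "nSignificantEdges"),
        threshold = vapply(perGroup, `[[`, numeric(1), "threshold"),
        nClusters = vapply(perGroup, function(x) nClusters(x$clusters),
                           numeric(1)),
        row.names = NULL)
    diffSummary <- data.frame(
        comparison = names(differential),
        nDifferential = vapply(differential, function(d)
            sum(d$fdr < fdrCutoff, na.rm = TRUE), numeric(1)),
        row.names = NULL)

    bundle <- structure(list(profiles = profiles, rankProduct = rp,
                             pca = pca, groups = perGroup,
                             differential = differential,
                             summary = summary, diffSummary = diffSummary,
                             annotation = ann, fdrCutoff = fdrCutoff,
                             seed = seed),
                        class = "PipelineBundle")
    if (!is.null(outDir)) writeBundle(bundle, outDir)
    bundle
}

#' @export
print.PipelineBundle <- function(x, ...) {
    cat("PipelineBundle\n")
    print(x$summary)
    if (nrow(x$diffSummary)) {
        cat("differential correlations (fdr <", x$fdrCutoff, "):\n")
        print(x$diffSummary)
    }
    invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' Deterministic layout: one subdirectory per group plus shared tables.
#' Repeated runs with the same bundle are byte-identical.
#'
#' @param bundle a \code{\link{runPipeline}} result.
#' @param outDir output directory (created if needed).
#' @export
writeBundle <- function(bundle, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, f) utils::write.table(
        df, file.path(outDir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
    writeProfileMatrix(bundle$profiles,
                       file.path(outDir, "profiles_log2.tsv"),
                       file.path(outDir, "sample_metadata.tsv"))
    if (!is.null(bundle$rankProduct)) wtsv(bundle$rankProduct, "rank_product.tsv")
    wtsv(data.frame(sample = rownames(bundle$pca$scores),
                    bundle$pca$scores, check.names = FALSE), "pca_scores.tsv")
    wtsv(data.frame(metabolite = rownames(bundle$pca$loadings),
                    bundle$pca$loadings, check.names = FALSE),
         "pca_loadings.tsv")
    wtsv(bundle$summary, "summary.tsv")
    wtsv(bundle$diffSummary, "differential_summary.tsv")
    for (g in names(bundle$groups)) {
        gd <- file.path(outDir, g)
        dir.create(gd, showWarnings = FALSE)
        el <- bundle$groups[[g]]
        utils::write.table(el$correlations, file.path(gd, "correlations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(sweepTable(el$sweep), file.path(gd, "sweep.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeNetwork(el$network, file.path(gd, "network_edges.tsv"),
                     "edgelist")
        writeNetwork(el$network, file.path(gd, "network.graphml"), "graphml")
        writeClusters(el$clusters, file.path(gd, "clusters.json"))
        if (!is.null(el$assessment)) {
            a <- el$assessment
            jsonlite::write_json(
                list(S = a@S, empirical_p = a@empiricalP,
                     n_random = a@nRandom, null_S = a@nullS,
                     per_cluster = perClusterEnrichment(a)),
                file.path(gd, "assessment.json"),
                auto_unbox = TRUE, digits = NA, dataframe = "rows",
                pretty = TRUE)
        }
    }
    for (nm in names(bundle$differential))
        wtsv(bundle$differential[[nm]],
             sprintf("differential_%s.tsv", nm))
    jsonlite::write_json(
        list(seed = bundle$seed, fdr_cutoff = bundle$fdrCutoff,
             groups = names(bundle$groups),
             package_version = as.character(utils::packageVersion("metcornet")),
             r_version = paste(R.version$major, R.version$minor, sep = ".")),
        file.path(outDir, "run_config.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(NULL)
}

#' Compare correlation structure between two analysis bundles
#'
#' Restricts both bundles to their common metabolites (exact-string
#' intersection), then for every group label present in both runs the
#' Fisher Z differential-correlation test with local fdr over the shared
#' pairs, reporting the number of differential pairs at the fdr cutoff.
#'
#' @param bundleA,bundleB \code{\link{runPipeline}} results (e.g. two
#'   tissues).
#' @param fdrCutoff significance level (default 0.05).
#' @return list: \code{commonMetabolites}, \code{tables} (per shared group
#'   label, the differential table) and \code{counts} (data.frame group,
#'   nDifferential).
#' @export
compareConditions <- function(bundleA, bundleB, fdrCutoff = 0.05) {
    common <- intersect(rownames(bundleA$profiles),
                        rownames(bundleB$profiles))
    stopIfNot(length(common) >= 4,
              "need >= 4 common metabolites (got %d)", length(common))
    message(sprintf("restricting to %d common metabolites", length(common)))
    sharedGroups <- intersect(names(bundleA$groups), names(bundleB$groups))
    stopIfNot(length(sharedGroups) > 0, "bundles share no group labels")
    inCommon <- function(d) d[d$u %in% common & d$v %in% common, ]
    tables <- lapply(sharedGroups, function(g) {
        differentialCorrelations(inCommon(bundleA$groups[[g]]$correlations),
                                 inCommon(bundleB$groups[[g]]$correlations))
    })
    names(tables) <- sharedGroups
    counts <- data.frame(
        group = sharedGroups,
        nDifferential = vapply(tables, function(d)
            sum(d$fdr < fdrCutoff, na.rm = TRUE), numeric(1)),
        row.names = NULL)
    list(commonMetabolites = common, tables = tables, counts = counts)
}
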