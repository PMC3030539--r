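#' Configuration for the synthetic metabolite-profile generator
#'
#' Defines a simulated metabolomics study: blocks of co-regulated
#' metabolites driven by latent factors (one factor per module), additive
#' genotype mean shifts on the log2 scale, Gaussian residual noise and a
#' heavy-tailed outlier contamination. Defaults emulate a three-genotype
#' Arabidopsis root profiling design: 59 metabolites over 53 samples
#' (WT n = 17, mto1 n = 16, tt4 n = 20), four correlated modules, and a
#' methionine-like +2 log2 over-accumulation in mto1.
#'
#' @param nMetabolites total number of metabolites.
#' @param moduleSizes integer vector of planted module sizes (each >= 2,
#'   sum <= nMetabolites). Use \code{integer(0)} for no modules.
#' @param groups named integer vector: group label -> number of samples.
#' @param factorLoading per-metabolite coefficient on its module's latent
#'   factor (all positive: metabolomic correlations are predominantly
#'   positive).
#' @param noiseSd log2-scale residual standard deviation.
#' @param shiftSpec data.frame with columns \code{group},
#'   \code{metabolite} (1-based index) and \code{shift} (log2 offset);
#'   \code{NULL} for no shifts.
#' @param outlierFraction probability that an entry's residual is inflated.
#' @param outlierScale multiplier (>= 1) applied to outlier residuals.
#' @param seed integer seed; required, generation is fully deterministic
#'   (Mersenne-Twister with inversion normals).
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(seed = 1)
#' sim <- generateProfiles(cfg)
#' dim(profileValues(sim$profiles))  # 59 x 53
#' @export
syntheticConfig <- function(nMetabolites = 59L,
                            moduleSizes = c(12L, 10L, 8L, 6L),
                            groups = c(WT = 17L, mto1 = 16L, tt4 = 20L),
                            factorLoading = 1.0,
                            noiseSd = 0.5,
                            shiftSpec = data.frame(
                                group = "mto1",
                                metabolite = 1:3,
                                shift = 2),
                            outlierFraction = 0.02,
                            outlierScale = 5,
                            seed) {
    stopIfNot(!missing(seed) && length(seed) == 1 && is.finite(seed),
              "'seed' is required and must be a single integer")
    nMetabolites <- as.integer(nMetabolites)
    moduleSizes <- as.integer(moduleSizes)
    stopIfNot(nMetabolites >= 1, "nMetabolites must be >= 1")
    stopIfNot(all(moduleSizes >= 2L), "every module size must be >= 2")
    stopIfNot(sum(moduleSizes) <= nMetabolites,
              "sum(moduleSizes) = %d exceeds nMetabolites = %d",
              sum(moduleSizes), nMetabolites)
    stopIfNot(!is.null(names(groups)) && all(groups >= 1),
              "'groups' must be a named vector of positive sample counts")
    stopIfNot(factorLoading > 0, "factorLoading must be > 0")
    stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
    stopIfNot(outlierFraction >= 0 && outlierFraction <= 1,
              "outlierFraction must be in [0,1]")
    stopIfNot(outlierScale >= 1, "outlierScale must be >= 1")
    if (!is.null(shiftSpec) && nrow(shiftSpec)) {
        stopIfNot(all(c("group", "metabolite", "shift") %in% colnames(shiftSpec)),
                  "shiftSpec needs columns group, metabolite, shift")
        stopIfNot(all(shiftSpec$metabolite >= 1 &
                      shiftSpec$metabolite <= nMetabolites),
                  "shiftSpec metabolite indices must be in [1, nMetabolites]")
        stopIfNot(all(shiftSpec$group %in% names(groups)),
                  "shiftSpec group labels must appear in 'groups'")
    }
    structure(list(nMetabolites = nMetabolites, moduleSizes = moduleSizes,
                   groups = groups, factorLoading = factorLoading,
                   noiseSd = noiseSd, shiftSpec = shiftSpec,
                   outlierFraction = outlierFraction,
                   outlierScale = outlierScale, seed = as.integer(seed)),
              class = "SyntheticConfig")
}

#' Generate synthetic metabolite profiles with planted structure
#'
#' Metabolite \eqn{i} in module \eqn{m} takes the log2-scale value
#' \eqn{\mu_i + shift(group, i) + \lambda f_{m,s} + \epsilon_{i,s}} with
#' \eqn{f_{m,s}} standard normal per sample, \eqn{\epsilon} normal with sd
#' \code{noiseSd}; with probability \code{outlierFraction} a residual is
#' multiplied by \code{outlierScale}. Metabolites outside all modules are
#' independent noise. Baselines \eqn{\mu_i} are uniform on [8, 12]
#' (typical log2 relative peak areas).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return A list with \code{profiles} (a
#'   \linkS4class{MetaboliteProfiles}, log2 scale) and \code{truth}, a list
#'   with \code{moduleMembership} (named integer, NA outside modules),
#'   \code{shiftedMetabolites} (list group -> metabolite ids) and
#'   \code{pathwayTruth} (module id -> pathway label).
#' @export
generateProfiles <- function(config) {
    stopIfNot(inherits(config, "SyntheticConfig"),
              "config must come from syntheticConfig()")
    n <- config$nMetabolites
    nMod <- length(config$moduleSizes)
    metIds <- sprintf("met%03d", seq_len(n))
    sampleIds <- unlist(lapply(names(config$groups), function(g)
        sprintf("%s_%02d", g, seq_len(config$groups[[g]]))), use.names = FALSE)
    groupOf <- rep(names(config$groups), config$groups)
    nS <- length(sampleIds)

    membership <- rep(NA_integer_, n)
    if (nMod) {
        bounds <- cumsum(config$moduleSizes)
        starts <- c(1L, head(bounds, -1L) + 1L)
        for (m in seq_len(nMod)) membership[starts[m]:bounds[m]] <- m
    }
    names(membership) <- metIds

    vals <- withSeed(config$seed, {
        mu <- runif(n, 8, 12)
        fac <- if (nMod) matrix(rnorm(nMod * nS), nMod, nS) else NULL
        eps <- matrix(rnorm(n * nS, sd = config$noiseSd), n, nS)
        if (config$outlierFraction > 0 && config$outlierScale > 1) {
            hit <- matrix(runif(n * nS) < config$outlierFraction, n, nS)
            eps[hit] <- eps[hit] * config$outlierScale
        }
        x <- matrix(mu, n, nS) + eps
        if (nMod) {
            inMod <- !is.na(membership)
            x[inMod, ] <- x[inMod, ] +
                config$factorLoading * fac[membership[inMod], , drop = FALSE]
        }
        x
    })
    if (!is.null(config$shiftSpec) && NROW(config$shiftSpec)) {
        for (k in seq_len(nrow(config$shiftSpec))) {
            g <- config$shiftSpec$group[k]
            i <- config$shiftSpec$metabolite[k]
            vals[i, groupOf == g] <- vals[i, groupOf == g] +
                config$shiftSpec$shift[k]
        }
    }
    dimnames(vals) <- list(metIds, sampleIds)

    shifted <- list()
    if (!is.null(config$shiftSpec) && NROW(config$shiftSpec)) {
        sp <- config$shiftSpec[config$shiftSpec$shift != 0, , drop = FALSE]
        shifted <- split(metIds[sp$metabolite], sp$group)
        shifted <- lapply(shifted, unique)
    }
    pathwayTruth <- if (nMod) {
        stats::setNames(sprintf("pw_module%d", seq_len(nMod)), seq_len(nMod))
    } else character(0)

    profiles <- MetaboliteProfiles(vals, groups = groupOf, scale = "log2")
    list(profiles = profiles,
         truth = list(moduleMembership = membership,
                      shiftedMetabolites = shifted,
                      pathwayTruth = pathwayTruth))
}

#' Emit a pathway annotation matching the planted modules
#'
#' Each planted module becomes one pathway containing exactly its members;
#' decoy pathways are random metabolite sets of comparable size drawn from
#' the whole universe (metabolites may carry several labels, as pathways
#' overlap in real annotations).
#'
#' @param truth the \code{truth} component of \code{\link{generateProfiles}}.
#' @param nDecoyPathways number of random decoy pathways (>= 0).
#' @param seed integer seed for the decoy draws.
#' @return A \linkS4class{PathwayAnnotation} whose universe is every
#'   simulated metabolite.
#' @export
generatePathwayAnnotation <- function(truth, nDecoyPathways = 4L, seed) {
    stopIfNot(nDecoyPathways >= 0, "nDecoyPathways must be >= 0")
    stopIfNot(!missing(seed), "'seed' is required")
    membership <- truth$moduleMembership
    universe <- names(membership)
    mods <- sort(unique(membership[!is.na(membership)]))
    members <- lapply(mods, function(m) universe[which(membership == m)])
    names(members) <- truth$pathwayTruth[as.character(mods)]
    if (nDecoyPathways > 0) {
        sizes <- if (length(mods)) lengths(members) else 5L
        decoys <- withSeed(as.integer(seed), {
            lapply(seq_len(nDecoyPathways), function(k) {
                sz <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
                sort(sample(universe, sz))
            })
        })
        names(decoys) <- sprintf("pw_decoy%d", seq_len(nDecoyPathways))
        members <- c(members, decoys)
    }
    PathwayAnnotation(members, universe = universe)
}
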