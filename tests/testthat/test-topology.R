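test_that("network construction respects threshold and sign conventions", {
    ct <- data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"),
                     r = c(0.9, 0.6, -0.7))
    attr(ct, "metabolites") <- c("a", "b", "c", "d")
    g0 <- buildNetwork(ct, 0)
    expect_equal(igraph::ecount(g0), 2)  # negative edge excluded
    expect_equal(igraph::vcount(g0), 4)  # isolated node kept
    gAbs <- buildNetwork(ct, 0.65, onlyPositive = FALSE)
    expect_equal(igraph::ecount(gAbs), 2)
    g1 <- buildNetwork(ct, 1.0)
    expect_equal(igraph::ecount(g1), 0)
    ct$r[1] <- 1.0
    expect_equal(igraph::ecount(buildNetwork(ct, 1.0)), 1)
    expect_error(buildNetwork(ct, 1.5), "0,1")
})

test_that("graph metrics match frozen values on canonical graphs", {
    k4 <- graphMetrics(igraph::make_full_graph(4))
    expect_equal(k4$density, 1)
    expect_equal(k4$clusteringCoefficient, 1)
    expect_equal(k4$averageDegree, 3)
    expect_equal(k4$averagePathLength, 1)
    expect_identical(k4$nComponents, 1L)
    expect_identical(k4$nEdges, 6L)

    p4 <- graphMetrics(igraph::make_graph(~ a - b, b - c, c - d))
    expect_equal(p4$density, 0.5)
    expect_equal(p4$clusteringCoefficient, 0)
    expect_identical(p4$nEdges, 3L)
    expect_identical(p4$nComponents, 1L)

    e5 <- graphMetrics(igraph::make_empty_graph(5, directed = FALSE))
    expect_identical(e5$nComponents, 5L)
    expect_identical(e5$nEdges, 0L)
    expect_true(is.na(e5$clusteringCoefficient))
})

test_that("graph metrics agree with the brute-force BFS oracle", {
    set.seed(121)
    for (k in 1:25) {
        A <- randomGraph(12, runif(1, 0.1, 0.6))
        got <- graphMetrics(graphFromAdj(A))
        want <- oracleGraphMetrics(A)
        for (col in names(want))
            expect_equal(got[[col]], want[[col]], tolerance = 1e-12,
                         label = sprintf("%s (rep %d)", col, k))
    }
})

test_that("profile randomization preserves marginals and kills correlation", {
    sim <- generateProfiles(syntheticConfig(
        nMetabolites = 12L, moduleSizes = c(6L, 4L), groups = c(A = 30L),
        shiftSpec = NULL, seed = 131))
    rnd <- randomizeProfiles(sim$profiles, nRandom = 20, seed = 132)
    expect_length(rnd, 20)
    orig <- profileValues(sim$profiles)
    for (k in c(1, 20))
        expect_identical(t(apply(rnd[[k]], 1, sort)),
                         t(apply(orig, 1, sort)))
    meanR <- mean(vapply(rnd, function(m) {
        ct <- spearmanCorrelations(toyProfiles(m))
        mean(ct$r)
    }, numeric(1)))
    # expected |mean r| ~ 0 within Monte-Carlo error
    expect_lt(abs(meanR), 0.02)
    # determinism
    rnd2 <- randomizeProfiles(sim$profiles, nRandom = 20, seed = 132)
    expect_identical(rnd, rnd2)
})

test_that("threshold sweeps are monotone and anchored at zero", {
    sim <- generateProfiles(syntheticConfig(
        nMetabolites = 15L, moduleSizes = c(5L, 4L), groups = c(A = 25L),
        shiftSpec = NULL, seed = 141))
    ct <- spearmanCorrelations(sim$profiles)
    sw <- sweepThresholds(ct, gridStep = 0.05)
    expect_equal(sw$real$nEdges[1], sum(ct$r >= 0))
    expect_true(all(diff(sw$real$nEdges) <= 0))
    expect_equal(sw$real$density,
                 2 * sw$real$nEdges / (15 * 14), tolerance = 1e-12)
})

test_that("null bands sit below real transitivity for modular data", {
    sim <- generateProfiles(syntheticConfig(
        nMetabolites = 20L, moduleSizes = c(7L, 6L), groups = c(A = 30L),
        shiftSpec = NULL, seed = 151))
    ct <- spearmanCorrelations(sim$profiles)
    nulls <- randomizeProfiles(sim$profiles, nRandom = 20, seed = 152)
    sw <- sweepThresholds(ct, nullMatrices = nulls, gridStep = 0.05)
    tab <- sweepTable(sw)
    mid <- tab$threshold >= 0.3 & tab$threshold <= 0.7
    realT <- tab$clusteringCoefficient[mid]
    nullT <- tab$clusteringCoefficient_nullMean[mid]
    cmp <- !is.na(realT) & !is.na(nullT)
    expect_true(mean(realT[cmp] > nullT[cmp]) > 0.8)
})

test_that("threshold selection finds the first component transition", {
    # hand-built sweep: jump at 0.3 -> 0.4, grid too short for a plateau
    sw <- list(real = data.frame(threshold = seq(0.1, 0.5, 0.1),
                                 nComponents = c(1, 1, 1, 10, 12)))
    expect_equal(selectThreshold(sw), 0.3)
    # flat curve falls back to the default with a warning
    flat <- list(real = data.frame(threshold = seq(0, 1, 0.01),
                                   nComponents = rep(3, 101)))
    expect_warning(th <- selectThreshold(flat), "flat")
    expect_equal(th, 0.5)
    # override always wins
    expect_equal(selectThreshold(flat, override = 0.5), 0.5)
    # two-transition curve: selection anchors on the first plateau
    nc <- c(rep(1, 20), seq(2, 26, length.out = 15), rep(27, 40),
            seq(28, 59, length.out = 21), rep(59, 5))
    sw2 <- list(real = data.frame(threshold = seq(0, 1, 0.01),
                                  nComponents = round(nc)))
    th2 <- selectThreshold(sw2)
    expect_gte(th2, 0.3)
    expect_lte(th2, 0.5)
})

test_that("auto-selected thresholds separate within- from between-module r", {
    ths <- vapply(1:5, function(k) {
        sim <- generateProfiles(syntheticConfig(seed = 160 + k))
        ct <- suppressWarnings(spearmanCorrelations(sim$profiles))
        mm <- sim$truth$moduleMembership
        within <- !is.na(mm[ct$u]) & !is.na(mm[ct$v]) & mm[ct$u] == mm[ct$v]
        sep <- (stats::quantile(ct$r[!within], 0.95, names = FALSE) +
                stats::quantile(ct$r[within], 0.05, names = FALSE)) / 2
        th <- selectThreshold(sweepThresholds(ct))
        abs(th - sep)
    }, numeric(1))
    expect_lt(mean(ths), 0.1)
})
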