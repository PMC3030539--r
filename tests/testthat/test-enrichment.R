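test_that("over-representation p-values match the enumeration oracle", {
    universe <- sprintf("m%02d", 1:20)
    ann <- PathwayAnnotation(list(pw = universe[1:5]), universe = universe)
    enr <- fisherExactEnrichment(universe[1:4], ann)
    # a=4, pathway 5, cluster 4, universe 20: C(5,4) C(15,0) / C(20,4)
    expect_equal(enr$table$p, 5 / 4845, tolerance = 1e-12)
    expect_equal(enr$table$p, 0.00103199174407, tolerance = 1e-9)
    expect_true(enr$significant)
    # zero overlap: upper tail P(X >= 0) = 1
    enr0 <- fisherExactEnrichment(universe[10:13], ann)
    expect_equal(enr0$table$p, 1)
    # contingency margins
    expect_identical(enr$table$a + enr$table$b, 5L)
    expect_identical(enr$table$a + enr$table$c, 4L)
    expect_identical(with(enr$table, a + b + c + d), 20L)
})

test_that("implementation equals full hypergeometric enumeration (n <= 30)", {
    set.seed(181)
    for (k in 1:100) {
        N <- sample(8:30, 1)
        universe <- sprintf("u%02d", seq_len(N))
        K <- sample(1:(N - 1), 1)
        kC <- sample(1:(N - 1), 1)
        pw <- sample(universe, K)
        cl <- sample(universe, kC)
        a <- length(intersect(pw, cl))
        ann <- PathwayAnnotation(list(pw = pw), universe = universe)
        got <- fisherExactEnrichment(cl, ann)$table$p
        expect_equal(got, oracleHyperTail(a, K, kC, N), tolerance = 1e-12)
    }
})

test_that("clusters with no annotated member are n.s.", {
    ann <- PathwayAnnotation(list(pw = c("m1", "m2")),
                             universe = c("m1", "m2", "m3"))
    expect_message(enr <- fisherExactEnrichment(c("z1", "z2"), ann), "n.s.")
    expect_true(is.na(enr$pMin))
})

test_that("the S-value is the mean best p with documented edge cases", {
    expect_equal(sValue(c(0.01, 0.03)), 0.02)
    expect_equal(sValue(0.2), 0.2)
    # invariant to cluster order; adding a cluster at p_min = S is neutral
    expect_equal(sValue(c(0.03, 0.01)), sValue(c(0.01, 0.03)))
    expect_equal(sValue(c(0.01, 0.03, 0.02)), 0.02)
    expect_warning(s <- sValue(c(0.1, NA)), "excluded")
    expect_equal(s, 0.1)
    expect_error(suppressWarnings(sValue(c(NA_real_, NA_real_))), "p_min")
    expect_error(sValue(numeric(0)), "no clusters")
})

test_that("randomized cluster sets preserve sizes and are reproducible", {
    universe <- sprintf("m%02d", 1:30)
    clusters <- list(universe[1:5], universe[3:10], universe[11:13])
    sets <- randomizedClusterSets(clusters, universe, nRandom = 50, seed = 191)
    expect_length(sets, 50)
    for (s in sets) {
        expect_identical(lengths(s), lengths(clusters))
        expect_true(all(unlist(s) %in% universe))
        expect_true(all(vapply(s, anyDuplicated, 0L) == 0L))
    }
    sets2 <- randomizedClusterSets(clusters, universe, nRandom = 50, seed = 191)
    expect_identical(sets, sets2)
    expect_error(randomizedClusterSets(list(universe, "x"), universe[1:3],
                                       nRandom = 1, seed = 1), "larger")
})

test_that("random-cluster pathway overlap follows the hypergeometric law", {
    universe <- sprintf("m%02d", 1:30)
    pw <- universe[1:10]
    sets <- randomizedClusterSets(list(universe[1:6]), universe,
                                  nRandom = 400, seed = 201)
    ov <- vapply(sets, function(s) length(intersect(s[[1]], pw)), numeric(1))
    # E[X] = k K / N = 6 * 10 / 30 = 2, Var from the hypergeometric
    expect_equal(mean(ov), 2, tolerance = 0.15)
    expect_equal(stats::var(ov), 6 * (10 / 30) * (20 / 30) * (24 / 29),
                 tolerance = 0.3)
})

test_that("global permutation mode preserves overlap structure", {
    universe <- sprintf("m%02d", 1:20)
    clusters <- list(universe[1:6], universe[5:10])  # share 2 members
    sets <- randomizedClusterSets(clusters, universe, nRandom = 20, seed = 211,
                                  globalPermutation = TRUE)
    for (s in sets)
        expect_identical(length(intersect(s[[1]], s[[2]])), 2L)
})

test_that("planted modules assess as significant; the empirical p is never 0", {
    cfg <- syntheticConfig(nMetabolites = 40L, moduleSizes = c(8L, 7L, 6L),
                           groups = c(A = 12L), shiftSpec = NULL, seed = 221)
    sim <- generateProfiles(cfg)
    ann <- generatePathwayAnnotation(sim$truth, nDecoyPathways = 3L, seed = 222)
    modules <- split(names(sim$truth$moduleMembership),
                     sim$truth$moduleMembership)
    a <- assessClusters(unname(modules), ann, nRandom = 100, seed = 223)
    expect_lte(empiricalP(a), 0.05)
    expect_gt(empiricalP(a), 0)          # +1 correction
    expect_lt(sValueOf(a), mean(nullSValues(a)))
    expect_identical(length(nullSValues(a)), 100L)
    pc <- perClusterEnrichment(a)
    expect_identical(pc$bestPathway, unname(sim$truth$pathwayTruth))
})

test_that("random 'real' clusters give a roughly uniform empirical p", {
    universe <- sprintf("m%02d", 1:40)
    ann <- PathwayAnnotation(
        list(pwA = universe[1:8], pwB = universe[9:15], pwC = universe[16:21]),
        universe = universe)
    set.seed(231)
    ps <- vapply(1:30, function(k) {
        clusters <- lapply(c(6, 5, 4), function(n) sample(universe, n))
        empiricalP(assessClusters(clusters, ann, nRandom = 60,
                                  seed = 5000 + k))
    }, numeric(1))
    expect_gt(mean(ps), 0.3)
    expect_lt(mean(ps), 0.7)
})
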