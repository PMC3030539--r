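test_that("common-neighbor weights match hand calculations", {
    tri <- edgeNodeWeights(igraph::make_full_graph(3))
    expect_true(all(tri$edges$weight == 1))
    expect_true(all(tri$nodes == 2))

    star <- edgeNodeWeights(igraph::make_star(4, mode = "undirected"))
    expect_true(all(star$edges$weight == 0))
    expect_true(all(star$nodes == 0))

    k4 <- edgeNodeWeights(igraph::make_full_graph(4))
    expect_true(all(k4$edges$weight == 2))
    expect_true(all(k4$nodes == 6))
})

test_that("cluster property follows cp = E_nk / (d_k |N_k|)", {
    # triangle a-b-c plus node d
    g <- igraph::make_graph(~ a - b, b - c, a - c, d - a, d - b, d - c)
    expect_equal(clusterProperty("d", c("a", "b", "c"), g), 1)
    g2 <- igraph::make_graph(~ a - b, b - c, a - c, d - a, d - b)
    expect_equal(clusterProperty("d", c("a", "b", "c"), g2), 2 / 3)
    g3 <- igraph::make_graph(~ a - b, b - c, a - c, d - e)
    expect_equal(clusterProperty("d", c("a", "b", "c"), g3), 0)
    expect_error(clusterProperty("a", c("a", "b"), g), "outside")
    # zero-density cluster: candidate cannot be scored
    g4 <- igraph::make_graph(~ a, b, c - a, c - b)
    expect_true(is.na(clusterProperty("c", c("a", "b"), g4)))
})

test_that("two disjoint cliques come out as exactly those clusters", {
    g <- igraph::disjoint_union(igraph::make_full_graph(5),
                                igraph::make_full_graph(5))
    igraph::V(g)$name <- c(paste0("a", 1:5), paste0("b", 1:5))
    res <- runDPClus(g)
    expect_identical(nClusters(res), 2L)
    expect_setequal(clusterMembers(res)[[1]], paste0("a", 1:5))
    expect_setequal(clusterMembers(res)[[2]], paste0("b", 1:5))
    expect_true(all(clusterDensities(res) == 1))
    expect_length(unclusteredNodes(res), 0)
})

test_that("a single bridge does not merge two cliques", {
    g <- igraph::disjoint_union(igraph::make_full_graph(5),
                                igraph::make_full_graph(4))
    igraph::V(g)$name <- c(paste0("a", 1:5), paste0("b", 1:4))
    g <- igraph::add_edges(g, match(c("a1", "b1"), igraph::V(g)$name))
    res <- runDPClus(g)
    mem <- clusterMembers(res)
    expect_identical(length(mem), 2L)
    expect_setequal(mem[[1]], paste0("a", 1:5))
    expect_setequal(mem[[2]], paste0("b", 1:4))
})

test_that("a single edge forms a minimal cluster of density 1", {
    g <- igraph::make_graph(~ a - b, c)
    res <- runDPClus(g, DPClusParams(minClusterSize = 2L))
    expect_identical(nClusters(res), 1L)
    expect_setequal(clusterMembers(res)[[1]], c("a", "b"))
    expect_equal(clusterDensities(res), 1)
    expect_identical(unclusteredNodes(res), "c")
})

test_that("emitted clusters respect the density floor on random graphs", {
    set.seed(171)
    for (k in 1:10) {
        A <- randomGraph(15, 0.35)
        res <- runDPClus(graphFromAdj(A))
        if (nClusters(res) == 0) next
        expect_true(all(clusterDensities(res) >= 0.5))
        expect_true(all(lengths(clusterMembers(res)) >= 2))
    }
})

test_that("non-overlapping clusters are pairwise disjoint", {
    set.seed(172)
    for (k in 1:10) {
        A <- randomGraph(15, 0.4)
        res <- runDPClus(graphFromAdj(A),
                         DPClusParams(overlapping = FALSE))
        mem <- clusterMembers(res)
        if (length(mem) < 2) next
        all <- unlist(mem)
        expect_identical(anyDuplicated(all), 0L)
        expect_true(all(all %in% rownames(A)))
    }
})

test_that("clustering is deterministic with totally ordered tie-breaking", {
    set.seed(173)
    A <- randomGraph(20, 0.3)
    r1 <- runDPClus(graphFromAdj(A))
    r2 <- runDPClus(graphFromAdj(A))
    expect_identical(clusterMembers(r1), clusterMembers(r2))
    expect_identical(unclusteredNodes(r1), unclusteredNodes(r2))
    # node order in the input must not matter
    perm <- sample(20)
    B <- A[perm, perm]
    r3 <- runDPClus(graphFromAdj(B))
    expect_identical(clusterMembers(r1), clusterMembers(r3))
})

test_that("overlapping extension can re-use removed nodes", {
    # two K4s sharing node x: x is clustered once, then re-attached
    g <- igraph::make_full_graph(4)
    igraph::V(g)$name <- c("x", "a1", "a2", "a3")
    h <- igraph::make_full_graph(4)
    igraph::V(h)$name <- c("x2", "b1", "b2", "b3")
    u <- igraph::disjoint_union(g, h)
    u <- igraph::add_edges(u, match(c("x", "b1", "x", "b2", "x", "b3"),
                                    igraph::V(u)$name))
    u <- igraph::delete_vertices(u, "x2")
    res <- runDPClus(u)
    mem <- clusterMembers(res)
    expect_identical(length(mem), 2L)
    expect_true("x" %in% mem[[1]] && "x" %in% mem[[2]])
    ext <- res@clusters[[2]]$extendedMembers
    expect_identical(ext, "x")
    # without overlapping mode the second cluster misses x
    res2 <- runDPClus(u, DPClusParams(overlapping = FALSE))
    shared <- intersect(clusterMembers(res2)[[1]], clusterMembers(res2)[[2]])
    expect_length(shared, 0)
})

test_that("cluster adjacency connects bridged or overlapping clusters", {
    g <- igraph::disjoint_union(igraph::make_full_graph(4),
                                igraph::make_full_graph(4))
    igraph::V(g)$name <- c(paste0("a", 1:4), paste0("b", 1:4))
    res <- runDPClus(g)
    cg <- clusterAdjacency(res, g)
    expect_equal(igraph::ecount(cg), 0)
    gb <- igraph::add_edges(g, match(c("a1", "b1"), igraph::V(g)$name))
    resb <- runDPClus(gb)
    cgb <- clusterAdjacency(resb, gb)
    expect_equal(igraph::ecount(cgb), 1)
})

test_that("empty graphs yield empty results", {
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("a", "b")
    res <- runDPClus(g)
    expect_identical(nClusters(res), 0L)
    expect_setequal(unclusteredNodes(res), c("a", "b"))
})
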