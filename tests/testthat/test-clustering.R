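test_that("cohesiveness matches the closed formula", {
    tri <- unitNetwork(c("A-B", "B-C", "C-A"))
    expect_equal(cohesiveness(tri, c("A", "B", "C"), penalty = 0), 1)
    expect_equal(cohesiveness(tri, c("A", "B", "C"), penalty = 2), 1 / 3)
    # set with no internal edges
    path <- unitNetwork(c("A-B", "B-C"))
    expect_equal(cohesiveness(path, c("A", "C"), penalty = 0), 0)
    # boundary weight counted once per crossing edge
    expect_equal(cohesiveness(path, c("A", "B"), penalty = 0), 1 / 2)
    expect_error(cohesiveness(tri, character(0)), "non-empty")
})

test_that("cohesiveness never increases when adding an unconnected node", {
    set.seed(14)
    for (i in 1:10) {
        net <- randomConnectedGraph(8, 0.5)
        g2 <- igraph::add_vertices(networkGraph(net), 1,
                                   attr = list(name = "zz_lone"))
        net2 <- asPPINetwork(g2)
        s <- sample(networkNodes(net), 4)
        expect_lte(cohesiveness(net2, c(s, "zz_lone"), penalty = 2),
                   cohesiveness(net2, s, penalty = 2))
    }
})

test_that("growClusters recovers planted cliques and merges duplicates", {
    # two unit-weight K5 joined by one weak edge -> exactly the two cliques
    g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
    igraph::V(g)$name <- c(paste0("A", 1:5), paste0("B", 1:5))
    g <- igraph::add_edges(g, c(5, 6))
    igraph::E(g)$weight <- c(rep(1, 20), 0.1)
    cl <- growClusters(asPPINetwork(g))
    expect_length(clusterMembers(cl), 2)
    expect_setequal(clusterMembers(cl)[[1]], paste0("A", 1:5))
    expect_setequal(clusterMembers(cl)[[2]], paste0("B", 1:5))
    # single K4 -> one cluster equal to the clique
    k4 <- igraph::make_full_graph(4)
    igraph::V(k4)$name <- letters[1:4]
    igraph::E(k4)$weight <- 1
    cl4 <- growClusters(asPPINetwork(k4))
    expect_length(clusterMembers(cl4), 1)
    expect_setequal(clusterMembers(cl4)[[1]], letters[1:4])
    expect_length(unclusteredNodes(cl4), 0)
})

test_that("identical candidates merge at overlap score 1", {
    expect_equal(overlapScore(letters[1:4], letters[1:4]), 1)
    expect_equal(overlapScore(letters[1:4], letters[3:6]), 4 / 16)
    expect_equal(overlapScore(letters[1:2], letters[5:6]), 0)
})

test_that("cluster density equals internal weight over pair count", {
    expect_equal(clusterDensity(8.1, 6), 0.54)
    expect_equal(clusterDensity(5.4, 4), 0.9)
    expect_equal(clusterDensity(3, 3), 1)          # unit-weight K3
    expect_error(clusterDensity(1, 1), "singleton")
    # every emitted cluster satisfies the identity
    fx <- makePlantedNetwork(seed = 8, moduleSize = 10)
    st <- clusterStats(growClusters(fx$network))
    expect_equal(st$density,
                 clusterDensity(st$internal_weight, st$size))
})

test_that("cluster p-value is an exact one-sided Mann-Whitney when tie-free", {
    # 6 members, all in-weights above all out-weights: minimal attainable p
    # = 1 / choose(12, 6) by exact enumeration of rank arrangements
    set.seed(4)
    g <- igraph::make_full_graph(6)
    igraph::V(g)$name <- paste0("m", 1:6)
    g <- igraph::add_vertices(g, 6, attr = list(name = paste0("o", 1:6)))
    g <- igraph::add_edges(g, rbind(1:6, 7:12))
    igraph::E(g)$weight <- c(runif(15, 0.8, 1), runif(6, 0.01, 0.1))
    p <- clusterPvalue(asPPINetwork(g), paste0("m", 1:6))
    expect_equal(p, 1 / choose(12, 6))
    # in-weights identical to out-weights -> no evidence, p >= 0.5
    sq <- unitNetwork(c("a-b", "b-c", "c-d", "d-a"))
    expect_gte(clusterPvalue(sq, c("a", "b")), 0.5)
})

test_that("significant clusters are planted modules, not random node sets", {
    set.seed(77)
    ok <- 0; trials <- 20
    for (i in seq_len(trials)) {
        fx <- makePlantedNetwork(seed = 1000 + i)
        modules <- split(names(fx$membership), fx$membership)
        pm <- vapply(modules, function(m)
            clusterPvalue(fx$network, m), 1.0)
        rand <- sample(networkNodes(fx$network), 20)
        pr <- clusterPvalue(fx$network, rand)
        if (all(pm < 0.05) && pr >= 0.05) ok <- ok + 1
    }
    expect_gte(ok / trials, 0.95)
})

test_that("cluster hubs use one global degree percentile", {
    # star K1,9 plus a separate 9-clique: global degrees are 9 (star hub),
    # 1 x9 (leaves), 8 x9 (clique); sorted position (19-1)*0.9+1 = 17.2
    # falls between two 8s, so the interpolated threshold is 8
    g <- igraph::make_star(10, mode = "undirected") +
        igraph::make_full_graph(9)
    igraph::V(g)$name <- c("HUB", paste0("L", 1:9), paste0("C", 1:9))
    igraph::E(g)$weight <- 1
    net <- asPPINetwork(g)
    expect_equal(degreeThreshold(net, 90), 8)
    cl <- growClusters(net)
    cl <- selectClusterHubs(net, cl, 90)
    hubs <- unlist(clusterHubs(cl))
    expect_true(all(hubs %in% "HUB") || length(hubs) == 0)
    # in the 9-clique cluster no member exceeds the global threshold
    stats <- clusterStats(cl)
    cliqueRow <- which(vapply(clusterMembers(cl),
                              function(m) all(grepl("^C", m)), TRUE))
    if (length(cliqueRow))
        expect_equal(stats$n_hubs[cliqueRow], 0L)
    # all-equal degrees -> no hubs anywhere
    tri <- unitNetwork(c("A-B", "B-C", "C-A"))
    clt <- selectClusterHubs(tri, growClusters(tri), 90)
    expect_equal(sum(clusterStats(clt)$n_hubs), 0L)
})

test_that("growClusters is deterministic and reports the OUT group", {
    fx <- makePlantedNetwork(seed = 21)
    a <- growClusters(fx$network)
    b <- growClusters(fx$network)
    expect_identical(clusterMembers(a), clusterMembers(b))
    expect_setequal(c(unlist(clusterMembers(a)), unclusteredNodes(a)),
                    networkNodes(fx$network))
    path <- tempfile(fileext = ".tsv")
    writeClusters(selectClusterHubs(fx$network, a), path)
    tab <- utils::read.delim(path)
    expect_equal(tab$cluster_id[nrow(tab)], "OUT")
})
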