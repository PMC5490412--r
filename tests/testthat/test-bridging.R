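test_that("bridging coefficient matches closed forms on paths and stars", {
    path <- unitNetwork(c("A-B", "B-C"))
    expect_equal(unname(bridgingCoefficient(path, "B")), 0.25)
    star <- igraph::make_star(5, mode = "undirected")
    igraph::V(star)$name <- c("CTR", paste0("L", 1:4))
    igraph::E(star)$weight <- 1
    snet <- asPPINetwork(star)
    expect_equal(unname(bridgingCoefficient(snet, "CTR")), (1 / 4) / 4)
    expect_equal(unname(bridgingCoefficient(snet, "L1")), 1 / (1 / 4))
    # isolated node: 0 with a warning
    g <- igraph::add_vertices(star, 1, attr = list(name = "ZZ"))
    expect_warning(bc <- bridgingCoefficient(asPPINetwork(g)), "isolated")
    expect_equal(unname(bc["ZZ"]), 0)
})

test_that("current-flow betweenness matches the per-pair oracle", {
    set.seed(101)
    for (i in 1:30) {
        net <- randomConnectedGraph(sample(4:8, 1), 0.6)
        got <- randomWalkBetweenness(net)
        want <- currentFlowOracle(net)
        expect_lt(max(abs(got - want[names(got)])), 1e-9)
    }
})

test_that("current-flow betweenness totals match the oracle on random graphs", {
    set.seed(202)
    for (i in 1:20) {
        net <- randomConnectedGraph(sample(5:10, 1), 0.5)
        expect_equal(sum(randomWalkBetweenness(net)),
                     sum(currentFlowOracle(net)), tolerance = 1e-9)
    }
})

test_that("on trees current flow equals shortest-path betweenness", {
    set.seed(303)
    for (i in 1:10) {
        n <- sample(5:12, 1)
        t <- igraph::sample_tree(n)
        igraph::V(t)$name <- sprintf("n%02d", seq_len(n))
        igraph::E(t)$weight <- runif(n - 1, 0.3, 1)
        net <- asPPINetwork(t)
        rwbc <- randomWalkBetweenness(net)
        spb <- igraph::betweenness(t, weights = NA) / (n * (n - 1) / 2)
        expect_equal(rwbc, spb[names(rwbc)], tolerance = 1e-9)
    }
})

test_that("current flow is computed per component, isolated nodes score 0", {
    g <- igraph::make_graph(~ A - B, B - C) + igraph::make_graph(~ X - Y, Y - Z)
    g <- igraph::add_vertices(g, 1, attr = list(name = "LONE"))
    igraph::E(g)$weight <- 1
    r <- randomWalkBetweenness(asPPINetwork(g))
    expect_equal(unname(r["LONE"]), 0)
    expect_equal(unname(r["B"]), unname(r["Y"]))
    expect_gt(r["B"], r["A"])
    expect_equal(unname(r["A"]), unname(r["C"]))
})

test_that("bridging centrality is the product and peaks on planted bridges", {
    # barbell: two K5 joined through a 2-node path
    g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
    igraph::V(g)$name <- c(paste0("A", 1:5), paste0("B", 1:5))
    g <- igraph::add_vertices(g, 2, attr = list(name = c("P1", "P2")))
    g <- igraph::add_edges(g, c(5, 11, 11, 12, 12, 6))
    igraph::E(g)$weight <- 1
    sc <- bridgingCentrality(asPPINetwork(g))
    expect_equal(sc$br, sc$rwbc * sc$bcoeff)
    expect_setequal(sc$node[1:2], c("P1", "P2"))   # path interior on top
    # zero rwbc -> zero br (leaves of a star)
    star <- igraph::make_star(4, mode = "undirected")
    igraph::V(star)$name <- c("c", "l1", "l2", "l3")
    igraph::E(star)$weight <- 1
    scs <- bridgingCentrality(asPPINetwork(star))
    expect_equal(scs$br[scs$node == "l1"], 0)
    # deterministic across runs
    expect_identical(sc, bridgingCentrality(asPPINetwork(g)))
})

test_that("bridge selection takes the strict top percentile", {
    sc <- data.frame(node = letters[1:10], rwbc = 1, bcoeff = 1,
                     br = seq(0.1, 1, by = 0.1))
    sel <- selectBridgeNodes(sc, 90)
    expect_equal(sel$node, "j")            # exactly one of 10 distinct values
    expect_equal(nrow(selectBridgeNodes(
        data.frame(node = letters[1:5], rwbc = 1, bcoeff = 1, br = 0.5))), 0)
    expect_equal(selectBridgeNodes(sc, 0)$node, letters[2:10])
    expect_error(selectBridgeNodes(sc[1, ]), "at least 2")
})

test_that("S_tot combines rescaled annotation counts as a noisy OR", {
    bg <- c(sprintf("b%d", 1:4), sprintf("x%d", 1:20))
    mk <- function(counts) {
        # counts: per bridge (rows b1..b4), columns KEGG count, GO count
        ids <- c(sprintf("K%d", 1:3), sprintf("GO:%d", 1:2))
        gsets <- list(
            K1 = bg[which(counts[, 1] >= 1)], K2 = bg[which(counts[, 1] >= 2)],
            K3 = bg[which(counts[, 1] >= 3)],
            `GO:1` = bg[which(counts[, 2] >= 1)],
            `GO:2` = bg[which(counts[, 2] >= 2)])
        gsets <- lapply(gsets, function(g) if (length(g)) g else bg[20])
        annotationCatalog(ids, c("KEGG", "KEGG", "KEGG", "GO", "GO"),
                          ids, gsets, background = bg)
    }
    counts <- rbind(c(3, 0), c(1, 2), c(0, 0), c(2, 1))
    cat_ <- mk(counts)
    bridges <- data.frame(node = sprintf("b%d", 1:4), rwbc = 1, bcoeff = 1,
                          br = c(0.4, 0.3, 0.2, 0.1))
    sc <- scoreBridges(bridges, cat_, sprintf("K%d", 1:3),
                       sprintf("GO:%d", 1:2))
    sc <- sc[order(sc$node), ]
    expect_equal(sc$count_kegg, counts[, 1])
    expect_equal(sc$count_go, counts[, 2])
    # hand-expanded formula per bridge: S_i = count/max, noisy-OR combine
    sk <- counts[, 1] / max(counts[, 1])
    sg <- counts[, 2] / max(counts[, 2])
    expect_equal(sc$s_tot, 1 - (1 - sk) * (1 - sg))
    expect_equal(sc$s_tot[1], 1)           # S_KEGG = 1, S_GO = 0
    # monotone in each count; zero iff both counts zero
    expect_equal(sc$s_tot[3], 0)
    expect_true(all(sc$s_tot >= 0 & sc$s_tot <= 1))
})

test_that("S_tot closed-form values on unit and half inputs", {
    # two bridges engineered so S_KEGG/S_GO hit (1,0) and (0.5,0.5)
    bg <- c("u", "v", "pad1", "pad2")
    cat_ <- annotationCatalog(
        c("K1", "K2", "GO:1", "GO:2"), c("KEGG", "KEGG", "GO", "GO"),
        c("a", "b", "c", "d"),
        list(c("u", "v"), "u", c("u", "v"), "u"), background = bg)
    bridges <- data.frame(node = c("u", "v"), rwbc = 1, bcoeff = 1,
                          br = c(0.2, 0.1))
    sc <- scoreBridges(bridges, cat_, c("K1", "K2"), c("GO:1", "GO:2"))
    sc <- sc[order(sc$node), ]
    expect_equal(sc$s_kegg, c(1, 0.5))
    expect_equal(sc$s_go, c(1, 0.5))
    expect_equal(sc$s_tot, c(1, 0.75))     # 1 - (1-.5)(1-.5)
})

test_that("planted connectors are selected as bridges", {
    set.seed(11)
    hits <- 0; trials <- 25
    for (i in seq_len(trials)) {
        fx <- makePlantedNetwork(seed = 5000 + i)
        sel <- selectBridgeNodes(bridgingCentrality(fx$network), 90)
        if (fx$bridges %in% sel$node) hits <- hits + 1
    }
    expect_gte(hits / trials, 0.95)
})
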