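# Shared helpers: small graph builders and independent oracles.

# "A-B" edge strings -> PPINetwork with the given (recycled) weights
unitNetwork <- function(edges, weights = 1) {
    el <- do.call(rbind, strsplit(edges, "-", fixed = TRUE))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::E(g)$weight <- rep_len(weights, igraph::ecount(g))
    asPPINetwork(g)
}

# Independent current-flow betweenness oracle: full Laplacian pseudoinverse
# (MASS::ginv), one explicit unit-current solve per source-target pair,
# absolute node throughputs summed directly.
currentFlowOracle <- function(network) {
    g <- networkGraph(network)
    n <- igraph::vcount(g)
    W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    L <- diag(rowSums(W)) - W
    Ti <- MASS::ginv(L)
    res <- stats::setNames(numeric(n), igraph::V(g)$name)
    comp <- igraph::components(g)$membership
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (comp[s] != comp[t]) next
        V_ <- Ti[, s] - Ti[, t]
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            res[v] <- res[v] + 0.5 * sum(W[v, ] * abs(V_[v] - V_))
        }
    }
    for (ci in unique(comp)) {
        nc <- sum(comp == ci)
        if (nc >= 2) res[comp == ci] <- res[comp == ci] / (nc * (nc - 1) / 2)
    }
    res
}

# random connected weighted graph for oracle comparisons
randomConnectedGraph <- function(n, p = 0.5, wmin = 0.2, wmax = 1) {
    repeat {
        g <- igraph::sample_gnp(n, p)
        if (igraph::components(g)$no == 1) break
    }
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), wmin, wmax)
    asPPINetwork(g)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# write a tiny STRING-style links file from a data.frame
writeLinksFixture <- function(df, path = tempfile(fileext = ".tsv")) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}
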