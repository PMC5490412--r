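#' Bridging coefficient
#'
#' Ratio of a node's inverse degree to the sum of its neighbors' inverse
#' degrees, `D(n)^-1 / sum_{v in N(n)} D(v)^-1`, with unweighted degrees.
#' Nodes with low degree sitting next to high-degree neighbors score high —
#' the local signature of a bridge.  Isolated nodes are scored 0 (with a
#' warning): the coefficient is undefined without neighbors.
#'
#' @param network a [PPINetwork-class] object.
#' @param node a node name; if missing, coefficients for all nodes are
#'   returned.
#' @param weighted use weighted degrees (strength) instead of neighbor
#'   counts.  Default `FALSE`: the definition speaks of the number of
#'   neighbors.
#' @return named numeric vector of bridging coefficients.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' igraph::E(g)$weight <- 1
#' bridgingCoefficient(asPPINetwork(g), "B")   # 0.25
#' @export
bridgingCoefficient <- function(network, node = NULL, weighted = FALSE) {
    g <- network@graph
    deg <- if (weighted)
        igraph::strength(g, weights = igraph::E(g)$weight)
    else igraph::degree(g)
    labels <- igraph::V(g)$name
    adj <- igraph::as_adj_list(g, mode = "all")
    bc <- vapply(seq_along(labels), function(i) {
        if (deg[i] == 0) return(NA_real_)
        nb <- as.integer(adj[[i]])
        (1 / deg[i]) / sum(1 / deg[nb])
    }, 1.0)
    names(bc) <- labels
    if (anyNA(bc)) {
        warning("isolated node(s) have undefined bridging coefficient; ",
                "scored 0")
        bc[is.na(bc)] <- 0
    }
    if (!is.null(node)) bc[node] else bc
}

#' Random-walk (current-flow) betweenness centrality
#'
#' Betweenness measured over all electrical-current paths: edge weights act
#' as conductances, and for every source-target pair a unit current is
#' injected and the absolute current through each intermediate node is
#' accumulated.  Computed per connected component from the inverse of the
#' reduced Laplacian, with the per-edge pair sums evaluated by the sorted
#' rank formula; scores are normalized by the component's source-target
#' pair count.  Isolated nodes and nodes in 2-node components score 0.
#'
#' @param network a [PPINetwork-class] object.
#' @return named numeric vector of centralities.
#' @export
randomWalkBetweenness <- function(network) {
    g <- network@graph
    labels <- igraph::V(g)$name
    res <- stats::setNames(numeric(length(labels)), labels)
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
        vids <- which(comp$membership == ci)
        nc <- length(vids)
        if (nc < 3) next
        sub <- igraph::induced_subgraph(g, vids)
        W <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
        L <- diag(rowSums(W)) - W
        Tm <- matrix(0, nc, nc)
        Tm[-nc, -nc] <- solve(L[-nc, -nc, drop = FALSE])
        el <- igraph::as_edgelist(sub, names = FALSE)
        ew <- igraph::E(sub)$weight
        coefs <- 2 * seq_len(nc) - 1 - nc
        tot <- numeric(nc)
        for (e in seq_len(nrow(el))) {
            i <- el[e, 1]; j <- el[e, 2]
            y <- Tm[i, ] - Tm[j, ]
            # sum over all source-target pairs of |current| on this edge
            Se <- ew[e] * sum(coefs * sort(y))
            tot[i] <- tot[i] + Se / 2
            tot[j] <- tot[j] + Se / 2
        }
        # remove the throughput a node accrues in pairs where it is itself
        # the source or target (1/2 per such pair), then normalize
        b <- (tot - (nc - 1) / 2) / (nc * (nc - 1) / 2)
        res[igraph::V(sub)$name] <- pmax(b, 0)
    }
    res
}

#' Bridging centrality
#'
#' `BR(n) = RWBC(n) x BCoeff(n)`: the product of random-walk (current-flow)
#' betweenness and the bridging coefficient.  High-BR nodes carry much of
#' the information flow while sitting between, not inside, dense modules —
#' making them natural drug-target candidates.
#'
#' @param network a [PPINetwork-class] object.
#' @return `data.frame` with columns `node`, `rwbc`, `bcoeff`, `br`, sorted
#'   by decreasing `br` (ties by node name).
#' @export
bridgingCentrality <- function(network) {
    rwbc <- randomWalkBetweenness(network)
    bcoeff <- suppressWarnings(bridgingCoefficient(network))
    res <- data.frame(node = names(rwbc), rwbc = unname(rwbc),
                      bcoeff = unname(bcoeff[names(rwbc)]),
                      stringsAsFactors = FALSE)
    res$br <- res$rwbc * res$bcoeff
    res <- res[order(-res$br, res$node), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Select bridge nodes by BR percentile
#'
#' Keeps the nodes whose bridging centrality strictly exceeds the
#' linear-interpolation `percentile` of all BR values (the highest
#' percentiles, > 90% by default).
#'
#' @param scores `data.frame` from [bridgingCentrality()].
#' @param percentile BR percentile (default 90).
#' @return the subset of `scores` rows selected as bridge nodes.
#' @export
selectBridgeNodes <- function(scores, percentile = 90) {
    if (nrow(scores) < 2) stop("need at least 2 scored nodes")
    thr <- stats::quantile(scores$br, probs = percentile / 100, type = 7)
    scores[scores$br > thr, , drop = FALSE]
}

#' Rank bridge nodes by annotation relevance
#'
#' For each bridge gene, counts the reference KEGG pathways and reference
#' GO terms (those known to be related to the process under study) whose
#' catalog gene set contains it.  Each count is rescaled to \[0,1\] by
#' dividing by the per-category maximum over the bridge set (0 when the
#' maximum is 0; `rescale = "minmax"` uses min-max rescaling instead), and
#' combined with the noisy-OR style score
#' `S_tot = 1 - (1 - S_KEGG)(1 - S_GO)`.  Bridges are ranked by decreasing
#' `S_tot`, ties broken by `br` then node name.
#'
#' @param bridges `data.frame` of selected bridge rows from
#'   [selectBridgeNodes()] (columns `node`, `rwbc`, `bcoeff`, `br`).
#' @param catalog an [AnnotationCatalog-class].
#' @param referenceKegg,referenceGo character vectors of reference term ids.
#' @param rescale `"max"` (default) or `"minmax"`.
#' @return `data.frame` with columns `node`, `rwbc`, `bcoeff`, `br`,
#'   `count_kegg`, `count_go`, `s_kegg`, `s_go`, `s_tot`, `rank`.
#' @export
scoreBridges <- function(bridges, catalog, referenceKegg, referenceGo,
                         rescale = c("max", "minmax")) {
    rescale <- match.arg(rescale)
    if (nrow(bridges) == 0) stop("bridge set must be non-empty")
    countFor <- function(refIds) {
        sets <- catalog@genes[intersect(refIds, names(catalog@genes))]
        vapply(bridges$node, function(b)
            sum(vapply(sets, function(gs) b %in% gs, TRUE)), 1L)
    }
    ck <- countFor(referenceKegg)
    cg <- countFor(referenceGo)
    rescaleFun <- function(x) {
        if (rescale == "max") {
            if (max(x) == 0) rep(0, length(x)) else x / max(x)
        } else {
            if (max(x) == min(x)) rep(0, length(x))
            else (x - min(x)) / (max(x) - min(x))
        }
    }
    res <- bridges
    res$count_kegg <- unname(ck)
    res$count_go <- unname(cg)
    res$s_kegg <- rescaleFun(res$count_kegg)
    res$s_go <- rescaleFun(res$count_go)
    res$s_tot <- 1 - (1 - res$s_kegg) * (1 - res$s_go)
    res <- res[order(-res$s_tot, -res$br, res$node), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
    rownames(res) <- NULL
    res
}

#' Write the ranked bridge table
#'
#' @param scored `data.frame` from [scoreBridges()].
#' @param path output TSV path.
#' @export
writeBridgeRanking <- function(scored, path) {
    utils::write.table(scored, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
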