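#' Read a STRING-style protein-links table
#'
#' Parses a tab-separated evidence table (columns `protein_a`, `protein_b`,
#' one column per evidence channel, and `combined_score`) and applies the
#' two construction filters: the combined confidence must be strictly above
#' `minScore` (high-confidence associations only), and at least one of the
#' required evidence channels must support the interaction (score > 0).
#' Duplicate and reversed pairs are collapsed keeping the maximum combined
#' score; self-interactions are dropped.  Integer scores on the 0-999 STRING
#' scale are detected per column and divided by 1000.
#'
#' @param path path to the tab-separated links file.
#' @param minScore combined-score threshold in \[0,1\]; edges are kept when
#'   `combined_score > minScore`.  Default 0.7 (the conventional
#'   high-confidence cutoff).
#' @param requiredChannels character vector of channel column names; an edge
#'   qualifies if at least one has score > 0.  With
#'   `channelMode = "all"` every listed channel must be > 0.
#' @param channelMode `"any"` (default) or `"all"`.
#' @return a `data.frame` of qualifying edges with columns `protein_a`,
#'   `protein_b`, one column per channel, and `combined_score`, all scores
#'   on the \[0,1\] scale.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_a\tprotein_b\texperimental\tdatabase\tcombined_score",
#'              "A\tB\t500\t0\t800", "B\tA\t0\t300\t900", "A\tC\t100\t0\t650"),
#'            tsv)
#' readStringLinks(tsv)   # one edge A-B with combined 0.9
#' @export
readStringLinks <- function(path, minScore = 0.7,
                            requiredChannels = c("experimental", "database"),
                            channelMode = c("any", "all")) {
    channelMode <- match.arg(channelMode)
    stopifnot(is.numeric(minScore), minScore >= 0, minScore <= 1)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character")
    needed <- c("protein_a", "protein_b", requiredChannels, "combined_score")
    missing <- setdiff(needed, names(tab))
    if (length(missing))
        stop("links file is missing required column(s): ",
             paste(missing, collapse = ", "))
    scoreCols <- setdiff(names(tab), c("protein_a", "protein_b"))
    for (col in scoreCols) {
        v <- suppressWarnings(as.numeric(tab[[col]]))
        bad <- which(is.na(v) & !is.na(tab[[col]]) & nzchar(tab[[col]]))
        if (length(bad))
            stop("non-numeric score in column '", col, "' at data line ",
                 bad[1])
        # STRING publishes integer scores on a 0-999 scale; detect per column
        if (any(v > 1, na.rm = TRUE)) v <- v / 1000
        if (any(v < 0 | v > 1, na.rm = TRUE))
            stop("scores in column '", col, "' fall outside [0,1] after ",
                 "rescaling")
        tab[[col]] <- v
    }
    keep <- tab$combined_score > minScore
    ch <- as.matrix(tab[, requiredChannels, drop = FALSE]) > 0
    keep <- keep & if (channelMode == "any") rowSums(ch) > 0
                   else rowSums(ch) == length(requiredChannels)
    keep <- keep & (tab$protein_a != tab$protein_b)
    tab <- tab[which(keep), , drop = FALSE]
    if (nrow(tab) == 0) {
        rownames(tab) <- NULL
        return(tab)
    }
    a <- pmin(tab$protein_a, tab$protein_b)
    b <- pmax(tab$protein_a, tab$protein_b)
    tab$protein_a <- a
    tab$protein_b <- b
    # dedup unordered pairs keeping the max combined score
    o <- order(a, b, -tab$combined_score)
    tab <- tab[o, , drop = FALSE]
    tab <- tab[!duplicated(paste(tab$protein_a, tab$protein_b, sep = "\r")), ,
               drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' Build the seed-expanded weighted PPI network
#'
#' The node set is the seeds plus every gene linked to a seed by a
#' qualifying edge; the edge set is all qualifying edges with both endpoints
#' in that node set (the induced subgraph), weighted by the combined
#' confidence score.  Seeds absent from every edge are kept as isolated
#' nodes so the input gene list is never silently shrunk.
#'
#' @param seeds non-empty character vector of seed gene symbols.
#' @param edges `data.frame` of pre-filtered edges as returned by
#'   [readStringLinks()] (columns `protein_a`, `protein_b`,
#'   `combined_score`).
#' @param minScore threshold recorded on the result (metadata only; the
#'   edges are assumed already filtered).
#' @return a [PPINetwork-class] object.
#' @examples
#' e <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"),
#'                 combined_score = c(0.8, 0.9))
#' net <- buildNetwork("A", e)
#' networkNodes(net)   # "A" "B": C is not a seed neighbor
#' @export
buildNetwork <- function(seeds, edges, minScore = 0.7) {
    seeds <- unique(as.character(seeds))
    if (length(seeds) == 0 || all(!nzchar(seeds)))
        stop("seed gene list must be non-empty")
    touching <- edges$protein_a %in% seeds | edges$protein_b %in% seeds
    nodes <- unique(c(seeds,
                      edges$protein_a[touching], edges$protein_b[touching]))
    induced <- edges$protein_a %in% nodes & edges$protein_b %in% nodes
    keep <- edges[induced, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
        data.frame(from = keep$protein_a, to = keep$protein_b,
                   weight = keep$combined_score),
        directed = FALSE,
        vertices = data.frame(name = nodes))
    new("PPINetwork", graph = g, seeds = seeds, minScore = minScore)
}

#' Wrap an existing igraph as a PPINetwork
#'
#' For externally supplied or synthetic graphs (no seed-expansion
#' guarantee).  The graph must be simple, undirected, named, with weights in
#' (0, 1].
#'
#' @param graph an igraph object.
#' @param seeds optional seed gene symbols.
#' @return a [PPINetwork-class] object.
#' @export
asPPINetwork <- function(graph, seeds = character(0)) {
    new("PPINetwork", graph = graph, seeds = as.character(seeds),
        minScore = NA_real_)
}

#' @describeIn PPINetwork-class node (gene) symbols.
#' @param network,object a `PPINetwork`.
#' @export
networkNodes <- function(network) igraph::V(network@graph)$name

#' @describeIn PPINetwork-class edge table
#'   (`node_a`, `node_b`, `weight`).
#' @export
networkEdges <- function(network) {
    el <- igraph::as_edgelist(network@graph, names = TRUE)
    data.frame(node_a = el[, 1], node_b = el[, 2],
               weight = if (igraph::ecount(network@graph))
                   igraph::E(network@graph)$weight else numeric(0),
               stringsAsFactors = FALSE)
}

#' @describeIn PPINetwork-class seed gene symbols.
#' @export
seedGenes <- function(network) network@seeds

#' @describeIn PPINetwork-class unweighted degree of every node.
#' @export
nodeDegrees <- function(network)
    igraph::degree(network@graph, loops = FALSE)

#' @describeIn PPINetwork-class underlying igraph object.
#' @export
networkGraph <- function(network) network@graph

setMethod("show", "PPINetwork", function(object) {
    g <- object@graph
    cat("PPINetwork with", igraph::vcount(g), "nodes and",
        igraph::ecount(g), "edges\n")
    if (length(object@seeds))
        cat("  seeds (", length(object@seeds), "): ",
            paste(utils::head(object@seeds, 8), collapse = ", "),
            if (length(object@seeds) > 8) ", ..." else "", "\n", sep = "")
    if (!is.na(object@minScore))
        cat("  combined-score filter: >", object@minScore, "\n")
})

#' Degree percentile threshold
#'
#' Returns the given percentile of the unweighted-degree distribution over
#' all network nodes, computed with linear interpolation.  Callers select
#' hub nodes whose degree is strictly greater than the returned value, so a
#' non-integer threshold (e.g. 203.5 on a real PPI network) selects exactly
#' the top tail.
#'
#' @param network a [PPINetwork-class] object with at least 2 nodes.
#' @param percentile percentile in \[0, 100); default 90 (top 10% of
#'   degrees).
#' @return the degree threshold (numeric scalar).
#' @examples
#' g <- igraph::make_star(10, mode = "undirected")
#' igraph::V(g)$name <- LETTERS[1:10]
#' igraph::E(g)$weight <- 1
#' degreeThreshold(asPPINetwork(g), 90)
#' @export
degreeThreshold <- function(network, percentile = 90) {
    deg <- nodeDegrees(network)
    if (length(deg) < 2)
        stop("degree threshold requires a network with at least 2 nodes")
    stopifnot(percentile >= 0, percentile < 100)
    unname(stats::quantile(deg, probs = percentile / 100, type = 7))
}

#' Write / read a network as plain-text edge and node tables
#'
#' The edge list (`node_a`, `node_b`, `weight`) plus a node table
#' (`node`, `is_seed`, `degree`) round-trip the network exactly (weights to
#' full precision).
#'
#' @param network a [PPINetwork-class] object.
#' @param edgePath,nodePath output / input TSV paths.
#' @return `writeNetwork` returns the paths invisibly; `readNetwork`
#'   returns a [PPINetwork-class].
#' @export
writeNetwork <- function(network, edgePath, nodePath) {
    ed <- networkEdges(network)
    utils::write.table(format(ed, digits = 17, trim = TRUE, scientific = FALSE),
                       edgePath, sep = "\t", quote = FALSE, row.names = FALSE)
    nd <- data.frame(node = networkNodes(network),
                     is_seed = networkNodes(network) %in% seedGenes(network),
                     degree = unname(nodeDegrees(network)))
    utils::write.table(nd, nodePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(edges = edgePath, nodes = nodePath))
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(edgePath, nodePath) {
    ed <- utils::read.delim(edgePath, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "numeric"))
    nd <- utils::read.delim(nodePath, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
        data.frame(from = ed$node_a, to = ed$node_b, weight = ed$weight),
        directed = FALSE, vertices = data.frame(name = nd$node))
    asPPINetwork(g, seeds = nd$node[nd$is_seed])
}
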