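#' @import methods
NULL

setOldClass("igraph")

#' Weighted protein-protein interaction network
#'
#' An undirected simple graph whose nodes are gene/protein symbols and whose
#' edge weights are interaction confidence scores in (0, 1].  A subset of
#' nodes is flagged as the seed (input) genes the network was expanded from;
#' networks not built by [buildNetwork()] may carry no seeds and are then
#' treated as externally supplied.
#'
#' @slot graph an \pkg{igraph} undirected graph with a numeric `weight`
#'   edge attribute and character vertex names.
#' @slot seeds character vector of seed gene symbols (possibly empty).
#' @slot minScore the combined-score threshold the edges were filtered at
#'   (`NA_real_` for externally supplied graphs).
#'
#' @seealso [buildNetwork()], [readStringLinks()], [networkNodes()],
#'   [networkEdges()], [seedGenes()]
#' @export
setClass("PPINetwork",
    representation(graph = "igraph", seeds = "character",
                   minScore = "numeric"),
    prototype(seeds = character(0), minScore = NA_real_))

setValidity("PPINetwork", function(object) {
    g <- object@graph
    msg <- character(0)
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g) || igraph::any_multiple(g))
        msg <- c(msg, "graph must be simple (no loops or parallel edges)")
    if (is.null(igraph::vertex_attr(g, "name")))
        msg <- c(msg, "vertices must be named")
    w <- igraph::edge_attr(g, "weight")
    if (igraph::ecount(g) > 0) {
        if (is.null(w))
            msg <- c(msg, "edges must carry a 'weight' attribute")
        else if (any(!is.finite(w)) || any(w <= 0) || any(w > 1))
            msg <- c(msg, "edge weights must lie in (0, 1]")
    }
    if (!all(object@seeds %in% igraph::V(g)$name))
        msg <- c(msg, "all seeds must be network nodes")
    if (length(msg)) msg else TRUE
})

#' Overlapping network clusters
#'
#' Result of cohesiveness-based seed-and-grow clustering: a list of member
#' sets (clusters may overlap), per-cluster statistics mirroring the usual
#' cluster table (size, weighted density, internal/external weight, one-sided
#' Mann-Whitney p-value, hub count), the hub genes per cluster, and the
#' unclustered ("OUT") nodes.
#'
#' @slot members list of character vectors, one per cluster.
#' @slot hubs list of character vectors, hub genes per cluster (filled by
#'   [selectClusterHubs()]).
#' @slot stats `data.frame` with one row per cluster: `cluster_id`, `size`,
#'   `density`, `internal_weight`, `external_weight`, `p_value`, `n_hubs`.
#' @slot unclustered character vector of nodes in no cluster.
#'
#' @seealso [growClusters()], [clusterPvalue()], [selectClusterHubs()]
#' @export
setClass("ClusterSet",
    representation(members = "list", hubs = "list", stats = "data.frame",
                   unclustered = "character"))

setValidity("ClusterSet", function(object) {
    msg <- character(0)
    if (length(object@members) != nrow(object@stats))
        msg <- c(msg, "stats must have one row per cluster")
    if (length(object@hubs) &&
        length(object@hubs) != length(object@members))
        msg <- c(msg, "hubs must align with members")
    ok <- mapply(function(h, m) all(h %in% m), object@hubs, object@members)
    if (length(ok) && !all(ok))
        msg <- c(msg, "hubs must be subsets of their cluster members")
    if (length(msg)) msg else TRUE
})

#' Gene-set annotation catalog
#'
#' Maps KEGG pathway and GO term identifiers to gene sets, together with the
#' background gene universe used for enrichment tests.
#'
#' @slot terms `data.frame` with columns `term_id`, `category`
#'   (`"KEGG"` or `"GO"`) and `name`.
#' @slot genes named list of character vectors (gene sets), names matching
#'   `term_id`.
#' @slot background character vector, the gene universe.
#'
#' @seealso [readGmt()], [enrichTerms()]
#' @export
setClass("AnnotationCatalog",
    representation(terms = "data.frame", genes = "list",
                   background = "character"))

setValidity("AnnotationCatalog", function(object) {
    msg <- character(0)
    if (anyDuplicated(object@terms$term_id))
        msg <- c(msg, "term_ids must be unique")
    if (!all(object@terms$category %in% c("KEGG", "GO")))
        msg <- c(msg, "category must be 'KEGG' or 'GO'")
    if (!identical(names(object@genes), as.character(object@terms$term_id)))
        msg <- c(msg, "gene list names must match term_ids")
    if (!all(unlist(object@genes) %in% object@background))
        msg <- c(msg, "every term gene must belong to the background")
    if (length(msg)) msg else TRUE
})

#' Boolean network with inhibitor-dominant logic
#'
#' Per-node activator and inhibitor sets defining the synchronous update rule
#' `x_t' = OR(activators) AND NOT OR(inhibitors)`; a node with only
#' inhibitors updates to `NOT OR(inhibitors)`, and a node with no regulators
#' is an input, constant under update.
#'
#' @slot nodes ordered character vector of node names.
#' @slot activators named list (one entry per node) of activator names.
#' @slot inhibitors named list (one entry per node) of inhibitor names.
#'
#' @seealso [assembleBooleanNetwork()], [booleanStep()], [continuousModel()]
#' @export
setClass("BooleanNetwork",
    representation(nodes = "character", activators = "list",
                   inhibitors = "list"))

setValidity("BooleanNetwork", function(object) {
    msg <- character(0)
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node names must be unique")
    if (!identical(names(object@activators), object@nodes) ||
        !identical(names(object@inhibitors), object@nodes))
        msg <- c(msg, "activator/inhibitor lists must be named by node")
    regs <- unique(c(unlist(object@activators), unlist(object@inhibitors)))
    if (!all(regs %in% object@nodes))
        msg <- c(msg, "regulators must reference existing nodes")
    if (length(msg)) msg else TRUE
})

#' Continuous (ODE) transform of a Boolean network
#'
#' Parameters of the BooleCube/HillCube conversion: each node relaxes toward
#' the multilinear interpolation of its Boolean rule over the unit hypercube,
#' with regulator states optionally passed through (normalized) Hill
#' functions.  The state space is `[0,1]^n`.
#'
#' @slot network a [BooleanNetwork-class] object.
#' @slot method one of `"boolecube"`, `"hillcube"`, `"normalized_hillcube"`.
#' @slot hillN Hill exponent (> 0).
#' @slot hillK Hill threshold in (0, 1).
#' @slot tau per-node time scales (> 0), recycled to the node count.
#'
#' @seealso [continuousModel()], [continuousRate()], [integrateModel()]
#' @export
setClass("ContinuousModel",
    representation(network = "BooleanNetwork", method = "character",
                   hillN = "numeric", hillK = "numeric", tau = "numeric"))

setValidity("ContinuousModel", function(object) {
    msg <- character(0)
    if (!object@method %in% c("boolecube", "hillcube", "normalized_hillcube"))
        msg <- c(msg, "unknown method")
    if (object@hillN <= 0) msg <- c(msg, "hillN must be > 0")
    if (object@hillK <= 0 || object@hillK >= 1)
        msg <- c(msg, "hillK must lie in (0, 1)")
    if (length(object@tau) != length(object@network@nodes) ||
        any(object@tau <= 0))
        msg <- c(msg, "tau must be positive, one value per node")
    if (length(msg)) msg else TRUE
})

#' Monte-Carlo switch ranking
#'
#' Per-gene counts of simulations in which the continuous state ended on the
#' opposite side of 0.5 from its random initial value, under a fixed
#' treatment initialization.  Treatment-target nodes are excluded from the
#' ranking.
#'
#' @slot ranking `data.frame` with columns `node`, `switch_count`, `n_sims`,
#'   `frequency`, `rank`, sorted by rank.
#' @slot treatment named numeric vector of treatment node states.
#' @slot nSims number of Monte-Carlo simulations.
#' @slot seed RNG seed used.
#'
#' @seealso [simulateTreatment()]
#' @export
setClass("SwitchRanking",
    representation(ranking = "data.frame", treatment = "numeric",
                   nSims = "numeric", seed = "numeric"))
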