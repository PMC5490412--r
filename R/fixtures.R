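#' Synthetic planted-module network
#'
#' Generates a weighted network with known ground truth for benchmarking
#' every pipeline stage: `nModules` dense modules (within-module edges with
#' probability `pIn`, weights above the usual 0.7 confidence filter),
#' sparse low-weight noise edges between modules (probability `pOut`,
#' weights below the filter so score-filter behavior is exercised), and
#' `nBridges` connector nodes each wired to a few nodes of at least two
#' modules with high-confidence edges — the planted bridges.
#'
#' @param nModules number of modules (default 2).
#' @param moduleSize nodes per module (>= 3; default 20).
#' @param pIn within-module edge probability (default 0.9).
#' @param pOut between-module edge probability (default 0.02).
#' @param nBridges number of planted connector nodes (default 1).
#' @param bridgeDegree edges from each bridge into each module
#'   (default 3).
#' @param inWeights,outWeights,bridgeWeights weight ranges per edge class.
#' @param seed RNG seed.
#' @return list with `network` (a [PPINetwork-class]), `membership` (named
#'   module id per module node) and `bridges` (connector node names).
#' @examples
#' fx <- makePlantedNetwork(seed = 1)
#' fx$network       # 41 nodes
#' fx$bridges       # "BRIDGE_1"
#' @export
makePlantedNetwork <- function(nModules = 2, moduleSize = 20, pIn = 0.9,
                               pOut = 0.02, nBridges = 1, bridgeDegree = 3,
                               inWeights = c(0.7, 1),
                               outWeights = c(0.15, 0.4),
                               bridgeWeights = c(0.7, 1), seed = 1) {
    if (moduleSize < 3) stop("moduleSize must be at least 3")
    stopifnot(nModules >= 1, pIn >= 0, pIn <= 1, pOut >= 0, pOut <= 1)
    set.seed(seed)
    pad <- function(i) formatC(i, width = 2, flag = "0")
    moduleNames <- lapply(seq_len(nModules), function(m)
        paste0("M", m, "_", pad(seq_len(moduleSize))))
    bridgeNames <- if (nBridges > 0) paste0("BRIDGE_", seq_len(nBridges))
                   else character(0)
    edges <- list()
    rw <- function(k, range) stats::runif(k, range[1], range[2])
    addEdges <- function(a, b, w)
        edges[[length(edges) + 1L]] <<- data.frame(
            protein_a = a, protein_b = b, combined_score = w,
            stringsAsFactors = FALSE)
    for (m in seq_len(nModules)) {
        nm <- moduleNames[[m]]
        pairs <- utils::combn(nm, 2)
        on <- stats::runif(ncol(pairs)) < pIn
        if (any(on))
            addEdges(pairs[1, on], pairs[2, on], rw(sum(on), inWeights))
    }
    if (nModules > 1 && pOut > 0) {
        for (m1 in seq_len(nModules - 1)) for (m2 in (m1 + 1):nModules) {
            grid <- expand.grid(a = moduleNames[[m1]], b = moduleNames[[m2]],
                                stringsAsFactors = FALSE)
            on <- stats::runif(nrow(grid)) < pOut
            if (any(on))
                addEdges(grid$a[on], grid$b[on], rw(sum(on), outWeights))
        }
    }
    for (b in seq_along(bridgeNames)) {
        # wire each connector into >= 2 modules with a few edges each
        targets <- sample(seq_len(nModules), min(2, nModules))
        for (m in targets) {
            anchor <- sample(moduleNames[[m]], min(bridgeDegree, moduleSize))
            addEdges(rep(bridgeNames[b], length(anchor)), anchor,
                     rw(length(anchor), bridgeWeights))
        }
    }
    ed <- do.call(rbind, edges)
    allNodes <- c(unlist(moduleNames), bridgeNames)
    g <- igraph::graph_from_data_frame(
        data.frame(from = ed$protein_a, to = ed$protein_b,
                   weight = ed$combined_score),
        directed = FALSE, vertices = data.frame(name = allNodes))
    membership <- stats::setNames(rep(seq_len(nModules), each = moduleSize),
                                  unlist(moduleNames))
    list(network = asPPINetwork(g), membership = membership,
         bridges = bridgeNames)
}

#' Write a network as a STRING-style links table
#'
#' Emits the tab-separated dialect [readStringLinks()] expects, with
#' integer scores on the 0-999 scale; the combined score is split over the
#' `experimental` and `database` channels so both channel filters are
#' exercised.
#'
#' @param network a [PPINetwork-class].
#' @param path output TSV path.
#' @param seed RNG seed for the channel split.
#' @export
writeStringLinks <- function(network, path, seed = 1) {
    set.seed(seed)
    ed <- networkEdges(network)
    n <- nrow(ed)
    combined <- as.integer(round(ed$weight * 1000))
    expShare <- stats::runif(n)
    tab <- data.frame(
        protein_a = ed$node_a, protein_b = ed$node_b,
        neighborhood = 0L, coexpression = 0L,
        experimental = as.integer(round(combined * expShare)),
        database = as.integer(round(combined * (1 - expShare))),
        textmining = 0L,
        combined_score = combined)
    # make sure at least one required channel is strictly positive
    zero <- tab$experimental == 0 & tab$database == 0
    tab$experimental[zero] <- tab$combined_score[zero]
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write an annotation catalog in GMT format
#'
#' @param catalog an [AnnotationCatalog-class].
#' @param path output GMT path.
#' @export
writeGmt <- function(catalog, path) {
    lines <- vapply(seq_len(nrow(catalog@terms)), function(i)
        paste(c(catalog@terms$term_id[i], catalog@terms$name[i],
                catalog@genes[[i]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Synthetic annotation catalog
#'
#' Random KEGG-style and GO-style terms over a gene universe, with a few
#' "relevant" terms planted on a chosen gene subset so that reference-list
#' matching and bridge scoring can be tested with known answers.
#'
#' @param background gene universe.
#' @param nKegg,nGo number of terms per category (defaults 12 and 15).
#' @param termSize range of term sizes (default `c(5, 25)`).
#' @param relevantGenes genes every "relevant" reference term must contain
#'   (default none).
#' @param relevantPool optional gene pool the relevant terms are drawn
#'   from (e.g. the network nodes), so they are genuinely concentrated in
#'   that set; by default terms are drawn uniformly from the background.
#' @param nRelevant number of relevant terms per category (default 3).
#' @param seed RNG seed.
#' @return list with `catalog` (an [AnnotationCatalog-class]),
#'   `referenceKegg` and `referenceGo` (the planted relevant term ids).
#' @export
makeAnnotationCatalog <- function(background, nKegg = 12, nGo = 15,
                                  termSize = c(5, 25),
                                  relevantGenes = character(0),
                                  relevantPool = NULL,
                                  nRelevant = 3, seed = 1) {
    set.seed(seed)
    background <- unique(as.character(background))
    termSize <- pmin(termSize, length(background) - 1)
    stopifnot(termSize[1] >= 1)
    drawTerm <- function(withGenes, pool = background) {
        k <- sample(seq(termSize[1], termSize[2]), 1)
        extra <- sample(setdiff(pool, withGenes),
                        min(length(setdiff(pool, withGenes)),
                            max(0, k - length(withGenes))))
        unique(c(withGenes, extra))
    }
    keggIds <- sprintf("path%05d", seq_len(nKegg))
    goIds <- sprintf("GO:%07d", seq_len(nGo))
    refK <- utils::head(keggIds, nRelevant)
    refG <- utils::head(goIds, nRelevant)
    pool <- if (is.null(relevantPool)) background
            else unique(as.character(relevantPool))
    genes <- c(
        lapply(keggIds, function(id)
            if (id %in% refK) drawTerm(relevantGenes, pool)
            else drawTerm(character(0))),
        lapply(goIds, function(id)
            if (id %in% refG) drawTerm(relevantGenes, pool)
            else drawTerm(character(0))))
    catalog <- annotationCatalog(
        c(keggIds, goIds),
        c(rep("KEGG", nKegg), rep("GO", nGo)),
        c(paste("pathway", seq_len(nKegg)), paste("term", seq_len(nGo))),
        genes, background = background)
    list(catalog = catalog, referenceKegg = refK, referenceGo = refG)
}

#' Write signed regulations as a toy KGML document
#'
#' Produces a minimal well-formed KGML pathway whose relations round-trip
#' through [parseKgml()] to exactly the input regulations: one gene entry
#' per distinct node and one relation per regulation, subtype `activation`
#' for sign +1 and `inhibition` for sign -1.
#'
#' @param regulations `data.frame` with columns `source`, `target`, `sign`;
#'   may have zero rows.
#' @param path optional output path; when `NULL` the KGML text is returned.
#' @param pathwayName name attribute for the pathway element.
#' @return the KGML text (invisibly when written to `path`).
#' @export
makeToyKgml <- function(regulations, path = NULL,
                        pathwayName = "synthetic pathway") {
    stopifnot(all(c("source", "target", "sign") %in% names(regulations)))
    if (nrow(regulations) > 0 &&
        (any(!nzchar(regulations$source)) || any(!nzchar(regulations$target))))
        stop("node names must be non-empty")
    nodes <- unique(c(regulations$source, regulations$target))
    ids <- stats::setNames(seq_along(nodes), nodes)
    entryXml <- vapply(nodes, function(n) sprintf(
        '  <entry id="%d" name="%s" type="gene"/>', ids[[n]], n), "")
    relXml <- if (nrow(regulations)) vapply(seq_len(nrow(regulations)),
        function(i) {
            sub <- if (regulations$sign[i] > 0) "activation" else "inhibition"
            sprintf(paste0('  <relation entry1="%d" entry2="%d" ',
                           'type="PPrel">\n    <subtype name="%s" ',
                           'value="--&gt;"/>\n  </relation>'),
                    ids[[regulations$source[i]]],
                    ids[[regulations$target[i]]], sub)
        }, "") else character(0)
    txt <- paste(c(
        '<?xml version="1.0"?>',
        sprintf('<pathway name="%s" org="syn" number="00001" title="%s">',
                pathwayName, pathwayName),
        entryXml, relXml, "</pathway>"), collapse = "\n")
    if (!is.null(path)) {
        writeLines(txt, path)
        return(invisible(txt))
    }
    txt
}

#' Random signed regulation set
#'
#' Draws a simple random signed graph (no self-loops, no duplicate
#' source-target pairs) of a requested size, for scale testing of the
#' Boolean-network machinery.
#'
#' @param nNodes,nEdges graph size (e.g. 44 nodes / 49 edges for a
#'   pathway-scale model).
#' @param pActivation probability a regulation is activating (default 0.7).
#' @param seed RNG seed.
#' @return `data.frame` with columns `source`, `target`, `sign`.
#' @export
makeRandomRegulations <- function(nNodes, nEdges, pActivation = 0.7,
                                  seed = 1) {
    set.seed(seed)
    nodes <- sprintf("G%03d", seq_len(nNodes))
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    stopifnot(nEdges <= nrow(pairs))
    pick <- pairs[sample(nrow(pairs), nEdges), ]
    pick$sign <- ifelse(stats::runif(nEdges) < pActivation, 1L, -1L)
    rownames(pick) <- NULL
    pick
}

#' Synthetic log2 expression table
#'
#' Long-format expression values for a factorial design mirroring a
#' scratch-assay experiment: four conditions (no/yes scratch crossed with
#' no/yes treatment), two timepoints, three biological replicates.  Values
#' are `baseline + effect + N(0, noiseSd)`.
#'
#' @param genes gene symbols.
#' @param conditions condition labels (default the 2x2 scratch/treatment
#'   design).
#' @param timepoints timepoints in hours (default `c(1, 5)`).
#' @param replicates replicates per cell (>= 2; default 3).
#' @param effects `data.frame` with columns `gene`, `condition`,
#'   `timepoint`, `effect` (log2 fold change added to the baseline);
#'   unlisted cells have effect 0.
#' @param baseline baseline log2 expression (default 5).
#' @param noiseSd Gaussian noise SD (default 0.25).
#' @param seed RNG seed.
#' @return long-format `data.frame` with columns `gene`, `condition`,
#'   `timepoint`, `replicate`, `log2_expression`.
#' @export
makeExpressionTable <- function(genes,
                                conditions = c("noScratch-noTreat",
                                               "noScratch-yesTreat",
                                               "yesScratch-noTreat",
                                               "yesScratch-yesTreat"),
                                timepoints = c(1, 5), replicates = 3,
                                effects = NULL, baseline = 5,
                                noiseSd = 0.25, seed = 1) {
    if (replicates < 2) stop("need at least 2 replicates per group")
    set.seed(seed)
    grid <- expand.grid(gene = genes, condition = conditions,
                        timepoint = timepoints,
                        replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$gene, grid$condition, grid$timepoint,
                       grid$replicate), ]
    eff <- numeric(nrow(grid))
    if (!is.null(effects)) {
        key <- paste(grid$gene, grid$condition, grid$timepoint)
        ekey <- paste(effects$gene, effects$condition, effects$timepoint)
        hit <- match(key, ekey)
        eff[!is.na(hit)] <- effects$effect[hit[!is.na(hit)]]
    }
    grid$log2_expression <- baseline + eff +
        stats::rnorm(nrow(grid), 0, noiseSd)
    rownames(grid) <- NULL
    grid
}

#' Write an expression table as TSV
#'
#' @param table expression `data.frame`.
#' @param path output path.
#' @export
writeExpressionTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
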