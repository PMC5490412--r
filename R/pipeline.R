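#' Default pipeline configuration
#'
#' Returns the full configuration list with the documented defaults:
#' combined-score filter 0.7, enrichment alpha 0.001, cluster significance
#' 0.05, hub/bridge percentile 90, normalized HillCube dynamics (n = 3,
#' k = 0.5, tau = 1, horizon 10) with 1000 Monte-Carlo simulations.
#' Fields under `inputs` are file paths; `outdir` receives all artifacts.
#'
#' @param ... named overrides of top-level fields or sublists.
#' @return the configuration list.
#' @export
defaultConfig <- function(...) {
    cfg <- list(
        inputs = list(links = NULL, seeds = NULL, catalog = NULL,
                      reference_kegg = NULL, reference_go = NULL,
                      kgml = NULL, expression = NULL),
        outdir = ".",
        min_score = 0.7,
        required_channels = c("experimental", "database"),
        channel_mode = "any",
        alpha = 0.001,
        cluster_p = 0.05,
        hub_percentile = 90,
        bridge_percentile = 90,
        clustering = list(penalty = 2, min_size = 3, min_density = 0.3,
                          overlap = 0.8),
        bn = list(method = "normalized_hillcube", hill_n = 3, hill_k = 0.5,
                  tau = 1, horizon = 10, n_sims = 1000, seed = 1,
                  treatment = list(), clamp = FALSE),
        expr = list(condition_a = "noScratch-noTreat",
                    condition_b = "yesScratch-yesTreat", timepoint = 5)
    )
    over <- list(...)
    for (nm in names(over)) {
        if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
            cfg[[nm]][names(over[[nm]])] <- over[[nm]]
        else cfg[[nm]] <- over[[nm]]
    }
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown fields are rejected; missing fields fall back to
#' [defaultConfig()] values.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    base <- defaultConfig()
    unknown <- setdiff(names(raw), names(base))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg <- do.call(defaultConfig, raw)
    validateConfig(cfg)
    cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg configuration list.
#' @return the configuration, invisibly, or an error naming the offending
#'   field.
#' @export
validateConfig <- function(cfg) {
    chk <- function(ok, field, what)
        if (!isTRUE(ok)) stop("config field '", field, "' ", what)
    chk(is.numeric(cfg$min_score) && cfg$min_score >= 0 &&
        cfg$min_score <= 1, "min_score", "must lie in [0,1]")
    chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
        "alpha", "must lie in (0,1)")
    chk(is.numeric(cfg$cluster_p) && cfg$cluster_p > 0 && cfg$cluster_p < 1,
        "cluster_p", "must lie in (0,1)")
    chk(cfg$hub_percentile >= 0 && cfg$hub_percentile < 100,
        "hub_percentile", "must lie in [0,100)")
    chk(cfg$bridge_percentile >= 0 && cfg$bridge_percentile < 100,
        "bridge_percentile", "must lie in [0,100)")
    chk(cfg$channel_mode %in% c("any", "all"), "channel_mode",
        "must be 'any' or 'all'")
    chk(cfg$bn$method %in% c("boolecube", "hillcube",
                             "normalized_hillcube"),
        "bn$method", "must be a known transform")
    chk(cfg$bn$hill_n > 0, "bn$hill_n", "must be > 0")
    chk(cfg$bn$hill_k > 0 && cfg$bn$hill_k < 1, "bn$hill_k",
        "must lie in (0,1)")
    chk(cfg$bn$n_sims >= 1, "bn$n_sims", "must be >= 1")
    chk(cfg$bn$horizon > 0, "bn$horizon", "must be > 0")
    invisible(cfg)
}

#' Read a seed gene list (one symbol per line, '#' comments)
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
readSeedList <- function(path) {
    x <- sub("#.*$", "", readLines(path))
    x <- trimws(x)
    x[nzchar(x)]
}

.need <- function(path, what) {
    if (is.null(path))
        stop("config inputs$", what, " is required for this stage")
    if (!file.exists(path))
        stop("missing ", what, " input: ", path,
             " (run earlier stages or fix the path)")
    path
}

#' Run the prioritization pipeline
#'
#' Chains the stages: `build-net` (read links, filter, expand seeds),
#' `enrich` (catalog over-representation + reference matching), `cluster`
#' (cohesiveness clustering, significance filter, hub selection), `bridge`
#' (bridging centrality, percentile selection, annotation ranking),
#' `simulate` (KGML to Boolean network to ODE Monte-Carlo switch ranking)
#' and `expr-stats` (Welch tests + Stouffer summary).  `"all"` executes
#' build-net, enrich, cluster, bridge and simulate.  Every stage writes its
#' TSV artifact into `cfg$outdir`, and a JSON run manifest records inputs,
#' parameters, package version and seed.
#'
#' @param cfg configuration list (see [defaultConfig()]).
#' @param stages character vector of stage names, or `"all"`.
#' @param quiet suppress per-stage messages.
#' @return named list of stage results and artifact paths, invisibly.
#' @export
runPipeline <- function(cfg = defaultConfig(), stages = "all",
                        quiet = FALSE) {
    validateConfig(cfg)
    known <- c("build-net", "enrich", "cluster", "bridge", "simulate",
               "expr-stats")
    if (identical(stages, "all"))
        stages <- c("build-net", "enrich", "cluster", "bridge", "simulate")
    bad <- setdiff(stages, known)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- list()
    say <- function(...) if (!quiet) message("[", format(Sys.time(),
        "%H:%M:%S"), "] ", ...)
    art <- function(f) file.path(cfg$outdir, f)

    network <- NULL
    getNetwork <- function() {
        if (!is.null(network)) return(network)
        ep <- art("network_edges.tsv"); np <- art("network_nodes.tsv")
        if (!file.exists(ep) || !file.exists(np))
            stop("missing network artifact; run the build-net stage first")
        readNetwork(ep, np)
    }
    catalog <- NULL
    getCatalog <- function() {
        if (!is.null(catalog)) return(catalog)
        readGmt(.need(cfg$inputs$catalog, "catalog"))
    }

    if ("build-net" %in% stages) {
        say("build-net: reading links and expanding seeds")
        edges <- readStringLinks(.need(cfg$inputs$links, "links"),
                                 minScore = cfg$min_score,
                                 requiredChannels = cfg$required_channels,
                                 channelMode = cfg$channel_mode)
        seeds <- readSeedList(.need(cfg$inputs$seeds, "seeds"))
        network <- buildNetwork(seeds, edges, minScore = cfg$min_score)
        writeNetwork(network, art("network_edges.tsv"),
                     art("network_nodes.tsv"))
        out$network <- network
        say("build-net: ", length(networkNodes(network)), " nodes, ",
            nrow(networkEdges(network)), " edges")
    }
    if ("enrich" %in% stages) {
        say("enrich: hypergeometric over-representation")
        network <- getNetwork()
        catalog <- getCatalog()
        rows <- enrichTerms(networkNodes(network), catalog,
                            alpha = cfg$alpha)
        utils::write.table(rows, art("enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        refs <- c(if (!is.null(cfg$inputs$reference_kegg))
                      readTermList(cfg$inputs$reference_kegg),
                  if (!is.null(cfg$inputs$reference_go))
                      readTermList(cfg$inputs$reference_go))
        out$enrichment <- rows
        out$reference_match <- matchReference(rows, refs)
        say("enrich: ", sum(rows$significant), " significant terms, ",
            out$reference_match$count, " matching the reference lists")
    }
    if ("cluster" %in% stages) {
        say("cluster: cohesiveness growth")
        network <- getNetwork()
        cl <- growClusters(network,
                           penalty = cfg$clustering$penalty,
                           minSize = cfg$clustering$min_size,
                           minDensity = cfg$clustering$min_density,
                           overlapThreshold = cfg$clustering$overlap)
        cl <- selectClusterHubs(network, cl, cfg$hub_percentile)
        writeClusters(cl, art("clusters.tsv"))
        out$clusters <- cl
        say("cluster: ", length(clusterMembers(cl)), " clusters, ",
            sum(clusterStats(cl)$p_value < cfg$cluster_p),
            " significant at p < ", cfg$cluster_p)
    }
    if ("bridge" %in% stages) {
        say("bridge: bridging centrality and ranking")
        network <- getNetwork()
        scores <- bridgingCentrality(network)
        bridges <- selectBridgeNodes(scores, cfg$bridge_percentile)
        ranked <- if (!is.null(cfg$inputs$catalog) &&
                      !is.null(cfg$inputs$reference_kegg) &&
                      !is.null(cfg$inputs$reference_go)) {
            scoreBridges(bridges, getCatalog(),
                         readTermList(cfg$inputs$reference_kegg),
                         readTermList(cfg$inputs$reference_go))
        } else bridges
        writeBridgeRanking(ranked, art("bridges.tsv"))
        out$bridges <- ranked
        say("bridge: ", nrow(bridges), " bridge nodes selected")
    }
    if ("simulate" %in% stages) {
        say("simulate: Boolean network Monte-Carlo")
        regs <- parseKgml(.need(cfg$inputs$kgml, "kgml"))
        bn <- assembleBooleanNetwork(regs)
        treatment <- unlist(cfg$bn$treatment)
        if (length(treatment) == 0)
            stop("config field 'bn$treatment' must name at least one ",
                 "treatment node for the simulate stage")
        ranking <- simulateTreatment(
            bn, treatment, nSims = cfg$bn$n_sims, seed = cfg$bn$seed,
            method = cfg$bn$method, hillN = cfg$bn$hill_n,
            hillK = cfg$bn$hill_k, tau = cfg$bn$tau,
            horizon = cfg$bn$horizon, clampTreatment = cfg$bn$clamp)
        writeSwitchRanking(ranking, art("switch_ranking.tsv"))
        out$switch_ranking <- ranking
        say("simulate: ", cfg$bn$n_sims, " simulations on ",
            length(bnNodes(bn)), " nodes")
    }
    if ("expr-stats" %in% stages) {
        say("expr-stats: Welch tests + Stouffer summary")
        tab <- readExpressionTable(.need(cfg$inputs$expression,
                                         "expression"))
        res <- expressionTests(tab, cfg$expr$condition_a,
                               cfg$expr$condition_b, cfg$expr$timepoint)
        utils::write.table(res$per_gene, art("expression_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(z_combined = res$summary$z_combined,
                       p_combined = res$summary$p_combined,
                       n = res$summary$n),
            art("expression_summary.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        out$expression <- res
    }
    manifest <- list(
        package = "BridgeNet",
        version = as.character(utils::packageVersion("BridgeNet")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        stages = stages,
        inputs = cfg$inputs[!vapply(cfg$inputs, is.null, TRUE)],
        parameters = cfg[setdiff(names(cfg), c("inputs", "outdir"))])
    jsonlite::write_json(manifest, art("run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    out$manifest <- art("run_manifest.json")
    invisible(out)
}

#' Generate a complete set of synthetic pipeline inputs
#'
#' Writes into `dir` everything [runPipeline()] needs: a STRING-style
#' links table and seed list derived from a planted-module network, a GMT
#' annotation catalog with planted reference terms, the reference term-id
#' lists, a toy KGML pathway, and an expression table.  Returns a
#' configuration pointing at the generated files, plus the ground truth.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param nModules,moduleSize,pIn,pOut,nBridges planted network shape, see
#'   [makePlantedNetwork()].
#' @param kgmlNodes,kgmlEdges toy pathway size (defaults 44 and 49,
#'   pathway scale).
#' @return list with `config` and `truth` (network ground truth, reference
#'   term ids, treatment nodes).
#' @export
makeFixtureInputs <- function(dir, seed = 1, nModules = 2, moduleSize = 20,
                              pIn = 0.9, pOut = 0.02, nBridges = 1,
                              kgmlNodes = 44, kgmlEdges = 49) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fx <- makePlantedNetwork(nModules = nModules, moduleSize = moduleSize,
                             pIn = pIn, pOut = pOut, nBridges = nBridges,
                             seed = seed)
    p <- function(f) file.path(dir, f)
    writeStringLinks(fx$network, p("links.tsv"), seed = seed)
    # every module node is a seed so the filtered graph is fully retained
    writeLines(c("# synthetic seed genes", names(fx$membership)),
               p("seeds.txt"))
    # background = network genes plus 3x decoys (annotation universes are
    # much larger than any one network), with the relevant reference terms
    # concentrated in network genes: whole-network enrichment then behaves
    # like a real over-representation analysis
    nodes <- networkNodes(fx$network)
    decoys <- sprintf("DECOY_%04d", seq_len(3 * length(nodes)))
    cat_ <- makeAnnotationCatalog(c(nodes, decoys),
                                  termSize = c(8, 25),
                                  relevantGenes = fx$bridges,
                                  relevantPool = nodes,
                                  seed = seed)
    writeGmt(cat_$catalog, p("catalog.gmt"))
    writeLines(cat_$referenceKegg, p("reference_kegg.txt"))
    writeLines(cat_$referenceGo, p("reference_go.txt"))
    regs <- makeRandomRegulations(kgmlNodes, kgmlEdges, seed = seed)
    makeToyKgml(regs, p("pathway.xml"))
    treatment <- stats::setNames(1, regs$source[1])
    genes <- utils::head(names(fx$membership), 8)
    eff <- data.frame(gene = genes, condition = "yesScratch-yesTreat",
                      timepoint = 5, effect = 1.5)
    writeExpressionTable(makeExpressionTable(genes, effects = eff,
                                             seed = seed),
                         p("expression.tsv"))
    cfg <- defaultConfig(
        inputs = list(links = p("links.tsv"), seeds = p("seeds.txt"),
                      catalog = p("catalog.gmt"),
                      reference_kegg = p("reference_kegg.txt"),
                      reference_go = p("reference_go.txt"),
                      kgml = p("pathway.xml"),
                      expression = p("expression.tsv")),
        outdir = file.path(dir, "out"),
        bn = list(treatment = as.list(treatment), seed = seed))
    list(config = cfg,
         truth = list(membership = fx$membership, bridges = fx$bridges,
                      referenceKegg = cat_$referenceKegg,
                      referenceGo = cat_$referenceGo,
                      treatment = treatment))
}
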