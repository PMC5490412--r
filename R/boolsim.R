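#' Parse KGML pathway XML into signed regulations
#'
#' Reads a KGML (KEGG Markup Language) document and translates its
#' `relation` elements into signed regulations: subtypes `activation` and
#' `expression` give sign +1, `inhibition` and `repression` give sign -1.
#' Relations with neither subtype are skipped with a warning.  Entries of
#' type `group` are expanded to one regulation per component.  Gene entries
#' whose `name` attribute lists several identifiers use the first.
#'
#' @param x KGML document: a file path, an XML string, or an `xml2`
#'   document.
#' @return `data.frame` with columns `source`, `target`, `sign`.
#' @export
parseKgml <- function(x) {
    doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
    entries <- xml2::xml_find_all(doc, ".//entry")
    ids <- xml2::xml_attr(entries, "id")
    types <- xml2::xml_attr(entries, "type")
    rawNames <- xml2::xml_attr(entries, "name")
    firstName <- vapply(strsplit(rawNames, "\\s+"), `[`, "", 1L)
    # a group entry stands for its component entries
    components <- lapply(entries, function(e)
        xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id"))
    names(components) <- ids
    resolve <- function(id) {
        i <- match(id, ids)
        if (is.na(i))
            stop("relation references unknown entry id '", id, "'")
        if (identical(types[i], "group")) {
            comp <- components[[i]]
            if (length(comp) == 0)
                stop("group entry '", id, "' has no components")
            unlist(lapply(comp, resolve))
        } else firstName[i]
    }
    relations <- xml2::xml_find_all(doc, ".//relation")
    out <- list()
    nSkipped <- 0L
    for (rel in relations) {
        subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"),
                                   "name")
        sign <- if (any(subtypes %in% c("activation", "expression"))) 1L
                else if (any(subtypes %in% c("inhibition", "repression"))) -1L
                else NA_integer_
        if (is.na(sign)) { nSkipped <- nSkipped + 1L; next }
        src <- resolve(xml2::xml_attr(rel, "entry1"))
        tgt <- resolve(xml2::xml_attr(rel, "entry2"))
        out[[length(out) + 1L]] <- expand.grid(
            source = src, target = tgt, sign = sign,
            stringsAsFactors = FALSE)
    }
    if (nSkipped > 0)
        warning(nSkipped, " relation(s) without an activation/inhibition ",
                "subtype were skipped")
    if (length(out) == 0)
        return(data.frame(source = character(0), target = character(0),
                          sign = integer(0)))
    res <- unique(do.call(rbind, out))
    rownames(res) <- NULL
    res
}

#' Assemble a Boolean network from signed regulations
#'
#' Each target's synchronous rule is `OR(activators) AND NOT
#' OR(inhibitors)`; targets with only inhibitors update to
#' `NOT OR(inhibitors)`, and nodes with no regulators are inputs, constant
#' under update.  A regulator appearing with both signs on the same target
#' is kept in both sets (the inhibitor dominates through the AND NOT) and
#' is reported in a message.
#'
#' @param regulations `data.frame` with columns `source`, `target`, `sign`
#'   (+1 or -1), e.g. from [parseKgml()].
#' @param nodes optional node ordering / extra unregulated nodes; defaults
#'   to the union of sources and targets in order of appearance.
#' @return a [BooleanNetwork-class] object.
#' @export
assembleBooleanNetwork <- function(regulations, nodes = NULL) {
    stopifnot(all(regulations$sign %in% c(-1L, 1L)))
    if (is.null(nodes))
        nodes <- unique(c(regulations$source, regulations$target))
    nodes <- as.character(nodes)
    act <- lapply(nodes, function(t) sort(unique(
        regulations$source[regulations$target == t & regulations$sign == 1])))
    inh <- lapply(nodes, function(t) sort(unique(
        regulations$source[regulations$target == t & regulations$sign == -1])))
    names(act) <- names(inh) <- nodes
    both <- mapply(function(a, i) length(intersect(a, i)) > 0, act, inh)
    if (any(both))
        message("contradictory regulations on node(s) ",
                paste(nodes[both], collapse = ", "),
                "; the inhibitor dominates")
    new("BooleanNetwork", nodes = nodes, activators = act, inhibitors = inh)
}

#' @describeIn BooleanNetwork-class node names.
#' @param network,object a `BooleanNetwork`.
#' @export
bnNodes <- function(network) network@nodes

#' @describeIn BooleanNetwork-class activator sets (named list).
#' @export
bnActivators <- function(network) network@activators

#' @describeIn BooleanNetwork-class inhibitor sets (named list).
#' @export
bnInhibitors <- function(network) network@inhibitors

setMethod("show", "BooleanNetwork", function(object) {
    nReg <- sum(vapply(object@activators, length, 1L) +
                vapply(object@inhibitors, length, 1L))
    nin <- sum(vapply(object@nodes, function(n)
        length(object@activators[[n]]) + length(object@inhibitors[[n]]) == 0,
        TRUE))
    cat("BooleanNetwork:", length(object@nodes), "nodes,", nReg,
        "regulations,", nin, "input node(s)\n")
})

#' Synchronous Boolean update
#'
#' Applies every node's rule simultaneously to a 0/1 state vector.
#'
#' @param network a [BooleanNetwork-class].
#' @param state 0/1 vector of length `length(bnNodes(network))`; names, if
#'   present, must match the node order.
#' @return the successor 0/1 state vector (named by node).
#' @export
booleanStep <- function(network, state) {
    nodes <- network@nodes
    if (length(state) != length(nodes))
        stop("state length must equal the number of nodes")
    state <- as.integer(state)
    names(state) <- nodes
    vapply(nodes, function(t) {
        a <- network@activators[[t]]
        i <- network@inhibitors[[t]]
        if (length(a) == 0 && length(i) == 0) return(state[[t]])
        actOn <- length(a) > 0 && any(state[a] == 1L)
        inhOn <- length(i) > 0 && any(state[i] == 1L)
        on <- if (length(a) == 0) !inhOn else actOn && !inhOn
        as.integer(on)
    }, 1L)
}

#' Continuous model of a Boolean network
#'
#' Packages the BooleCube/HillCube conversion parameters with a network.
#' Defaults follow common practice for this transform: normalized HillCube
#' with Hill exponent 3 and threshold 0.5, unit time scale.
#'
#' @param network a [BooleanNetwork-class].
#' @param method `"normalized_hillcube"` (default), `"hillcube"`, or
#'   `"boolecube"`.
#' @param hillN Hill exponent (default 3).
#' @param hillK Hill threshold in (0,1) (default 0.5).
#' @param tau time scale(s), recycled per node (default 1).
#' @return a [ContinuousModel-class] object.
#' @export
continuousModel <- function(network,
                            method = c("normalized_hillcube", "hillcube",
                                       "boolecube"),
                            hillN = 3, hillK = 0.5, tau = 1) {
    method <- match.arg(method)
    tau <- rep_len(tau, length(network@nodes))
    new("ContinuousModel", network = network, method = method,
        hillN = hillN, hillK = hillK, tau = tau)
}

setMethod("show", "ContinuousModel", function(object) {
    cat("ContinuousModel (", object@method, ", n = ", object@hillN,
        ", k = ", object@hillK, ") on ", length(object@network@nodes),
        " nodes\n", sep = "")
})

.hill <- function(x, n, k) x^n / (x^n + k^n)

# Multilinear (BooleCube) interpolation of the inhibitor-dominant rule.
# The rule OR(a) AND NOT OR(i) factorizes over disjoint regulator sets, so
# the interpolation is (1 - prod(1 - a)) * prod(1 - i).
.ruleValue <- function(a, i, hasAct) {
    orA <- if (hasAct) 1 - prod(1 - a) else 1
    orA * prod(1 - i)
}

#' Continuous rate of change
#'
#' `dx_t/dt = (B~_t(x) - x_t) / tau_t`, where `B~_t` is the multilinear
#' interpolation of node `t`'s Boolean rule over the unit hypercube.
#' Regulator states enter directly (`boolecube`), through Hill functions
#' `h(x) = x^n / (x^n + k^n)` (`hillcube`), or through normalized Hill
#' functions `h(x)/h(1)` (`normalized_hillcube`), which restore exact
#' agreement with the Boolean rule at the hypercube corners.  Input nodes
#' (no regulators) have zero rate.
#'
#' @param model a [ContinuousModel-class].
#' @param x state vector in `[0,1]^n` (named or in node order).
#' @return named derivative vector.
#' @export
continuousRate <- function(model, x) {
    nodes <- model@network@nodes
    if (length(x) != length(nodes))
        stop("state length must equal the number of nodes")
    if (any(x < -1e-9) || any(x > 1 + 1e-9))
        stop("state must lie in [0,1]^n")
    x <- pmin(pmax(as.numeric(x), 0), 1)
    names(x) <- nodes
    h <- switch(model@method,
        boolecube = function(v) v,
        hillcube = function(v) .hill(v, model@hillN, model@hillK),
        normalized_hillcube = function(v)
            .hill(v, model@hillN, model@hillK) /
            .hill(1, model@hillN, model@hillK))
    target <- vapply(nodes, function(t) {
        a <- model@network@activators[[t]]
        i <- model@network@inhibitors[[t]]
        if (length(a) == 0 && length(i) == 0) return(x[[t]])
        .ruleValue(h(x[a]), h(x[i]), hasAct = length(a) > 0)
    }, 1.0)
    (target - x) / model@tau
}

#' Integrate the continuous model
#'
#' Numerically solves the ODE system on `[0, horizon]` with `deSolve`.
#' Clamped nodes are held at their initial value throughout (their rate is
#' forced to zero), modeling a sustained stimulus.
#'
#' @param model a [ContinuousModel-class].
#' @param x0 initial state in `[0,1]^n` (named or in node order).
#' @param horizon integration time (default 10).
#' @param clamp character vector of nodes to hold fixed.
#' @param times output time grid (default 101 points on `[0, horizon]`).
#' @return matrix of the trajectory: first column `time`, one column per
#'   node.
#' @export
integrateModel <- function(model, x0, horizon = 10, clamp = character(0),
                           times = NULL) {
    nodes <- model@network@nodes
    if (length(x0) != length(nodes))
        stop("x0 length must equal the number of nodes")
    x0 <- stats::setNames(as.numeric(x0), nodes)
    if (any(x0 < 0) || any(x0 > 1)) stop("x0 must lie in [0,1]^n")
    if (!all(clamp %in% nodes)) stop("unknown clamp node")
    clampIdx <- match(clamp, nodes)
    if (is.null(times)) times <- seq(0, horizon, length.out = 101L)
    deriv <- function(t, y, parms) {
        dy <- continuousRate(model, y)
        if (length(clampIdx)) dy[clampIdx] <- 0
        list(dy)
    }
    sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    if (attr(sol, "istate")[1] < 0)
        stop("ODE solver failed: istate = ", attr(sol, "istate")[1])
    unclass(sol)
}

#' Monte-Carlo treatment simulation and switch ranking
#'
#' Simulates a treatment stimulus on the pathway: in each simulation the
#' treatment nodes start at their stated 0/1 values (optionally clamped for
#' the whole horizon) while every other node is initialized independently
#' to 0 or 1 with probability 1/2; the continuous model is integrated to
#' `horizon`, and a gene counts as switched when its final state lies on
#' the opposite side of 0.5 from its initial value.  Genes are ranked by
#' descending switch frequency across simulations (treatment nodes
#' excluded; ties broken by node name).  Initial states are drawn per node
#' name in lexicographic order, so the ranking is invariant to node
#' ordering and reproducible given the seed.
#'
#' @param network a [BooleanNetwork-class].
#' @param treatment named 0/1 vector of treatment node states.
#' @param nSims number of Monte-Carlo simulations (default 1000).
#' @param seed RNG seed.
#' @param method,hillN,hillK,tau continuous-transform parameters, see
#'   [continuousModel()].
#' @param horizon integration time (default 10).
#' @param clampTreatment hold treatment nodes fixed for the whole horizon
#'   (default `FALSE`: they are initialized only).
#' @param switchThreshold state threshold (default 0.5).
#' @return a [SwitchRanking-class] object.
#' @export
simulateTreatment <- function(network, treatment, nSims = 1000, seed = 1,
                              method = "normalized_hillcube", hillN = 3,
                              hillK = 0.5, tau = 1, horizon = 10,
                              clampTreatment = FALSE,
                              switchThreshold = 0.5) {
    nodes <- network@nodes
    if (!all(names(treatment) %in% nodes))
        stop("unknown treatment node(s): ",
             paste(setdiff(names(treatment), nodes), collapse = ", "))
    stopifnot(all(treatment %in% c(0, 1)), nSims >= 1)
    model <- continuousModel(network, method = method, hillN = hillN,
                             hillK = hillK, tau = tau)
    free <- setdiff(nodes, names(treatment))
    lexFree <- sort(free)
    set.seed(seed)
    # one Bernoulli(1/2) column per free node, drawn in lexicographic name
    # order: the same seed yields the same per-gene initial states whatever
    # the network's internal node order
    init <- matrix(0, nrow = nSims, ncol = length(lexFree),
                   dimnames = list(NULL, lexFree))
    for (nm in lexFree) init[, nm] <- stats::rbinom(nSims, 1, 0.5)
    clamp <- if (clampTreatment) names(treatment) else character(0)
    times <- c(0, horizon)
    switched <- stats::setNames(integer(length(nodes)), nodes)
    for (s in seq_len(nSims)) {
        x0 <- stats::setNames(numeric(length(nodes)), nodes)
        x0[names(treatment)] <- treatment
        x0[lexFree] <- init[s, ]
        traj <- integrateModel(model, x0, horizon = horizon, clamp = clamp,
                               times = times)
        final <- traj[nrow(traj), -1]
        sw <- (final > switchThreshold) != (x0 > switchThreshold) &
            final != switchThreshold & x0 != switchThreshold
        switched <- switched + as.integer(sw)
    }
    keep <- setdiff(nodes, names(treatment))
    ranking <- data.frame(node = keep,
                          switch_count = unname(switched[keep]),
                          n_sims = nSims,
                          frequency = unname(switched[keep]) / nSims,
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$frequency, ranking$node), ,
                       drop = FALSE]
    ranking$rank <- seq_len(nrow(ranking))
    rownames(ranking) <- NULL
    new("SwitchRanking", ranking = ranking,
        treatment = stats::setNames(as.numeric(treatment),
                                    names(treatment)),
        nSims = nSims, seed = seed)
}

#' @describeIn SwitchRanking-class the ranking table.
#' @param x,object a `SwitchRanking`.
#' @export
switchRanking <- function(x) x@ranking

setMethod("show", "SwitchRanking", function(object) {
    cat("SwitchRanking over", object@nSims, "simulations; treatment:",
        paste(names(object@treatment), "=", object@treatment,
              collapse = ", "), "\n")
    print(utils::head(object@ranking, 10), digits = 3)
})

#' Write the switch ranking
#'
#' @param ranking a [SwitchRanking-class].
#' @param path output TSV path.
#' @export
writeSwitchRanking <- function(ranking, path) {
    utils::write.table(ranking@ranking, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
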