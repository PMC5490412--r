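#' Cohesiveness of a node set
#'
#' The objective driving cluster growth:
#' `w_in / (w_in + w_bound + penalty * |S|)`, where `w_in` is the total
#' weight of edges inside the set and `w_bound` the total weight of edges
#' crossing its boundary.  The penalty term models unobserved interactions
#' and discourages loosely attached members.
#'
#' @param network a [PPINetwork-class] object.
#' @param nodeSet non-empty character vector of member nodes.
#' @param penalty non-negative per-node penalty (default 2).
#' @return the cohesiveness score in \[0, 1).
#' @export
cohesiveness <- function(network, nodeSet, penalty = 2) {
    nodeSet <- unique(as.character(nodeSet))
    if (length(nodeSet) == 0) stop("nodeSet must be non-empty")
    stopifnot(all(nodeSet %in% networkNodes(network)))
    ed <- networkEdges(network)
    inA <- ed$node_a %in% nodeSet
    inB <- ed$node_b %in% nodeSet
    win <- sum(ed$weight[inA & inB])
    wb <- sum(ed$weight[xor(inA, inB)])
    denom <- win + wb + penalty * length(nodeSet)
    if (denom == 0) return(0)
    win / denom
}

#' Overlap score between two clusters
#'
#' `omega(A, B) = |A intersect B|^2 / (|A| |B|)`.
#' @param a,b character vectors of members.
#' @return overlap score in \[0, 1\].
#' @export
overlapScore <- function(a, b) {
    length(intersect(a, b))^2 / (length(a) * length(b))
}

# Greedy local search from one seed node: grow/shrink the member set to a
# local maximum of cohesiveness.  W is the dense weighted adjacency matrix,
# strength its row sums.  Deterministic: among equally good moves the
# lexicographically smallest node label wins, additions preferred over
# removals.
.growFromSeed <- function(W, strength, labels, seedIdx, penalty) {
    n <- length(labels)
    members <- logical(n)
    members[seedIdx] <- TRUE
    w2c <- W[seedIdx, ]           # weight from every node to the cluster
    win <- 0
    wb <- strength[seedIdx]
    size <- 1L
    coh <- function(w_in, w_b, k) {
        d <- w_in + w_b + penalty * k
        if (d == 0) 0 else w_in / d
    }
    current <- coh(win, wb, size)
    repeat {
        # candidate additions: boundary nodes
        addIdx <- which(!members & w2c > 0)
        addCoh <- if (length(addIdx))
            (win + w2c[addIdx]) /
                (win + w2c[addIdx] +
                 (wb - w2c[addIdx] + strength[addIdx] - w2c[addIdx]) +
                 penalty * (size + 1))
        else numeric(0)
        # candidate removals (never empty the set)
        remIdx <- if (size > 1L) which(members) else integer(0)
        remCoh <- if (length(remIdx)) {
            wi <- win - w2c[remIdx]
            wbnd <- wb - (strength[remIdx] - w2c[remIdx]) + w2c[remIdx]
            ifelse(wi + wbnd + penalty * (size - 1) == 0, 0,
                   wi / (wi + wbnd + penalty * (size - 1)))
        } else numeric(0)
        best <- max(c(addCoh, remCoh, -Inf))
        if (!(best > current + 1e-12)) break
        tol <- best - 1e-12
        bestAdd <- addIdx[addCoh >= tol]
        bestRem <- remIdx[remCoh >= tol]
        if (length(bestAdd)) {
            v <- bestAdd[order(labels[bestAdd])][1]
            members[v] <- TRUE
            win <- win + w2c[v]
            wb <- wb - w2c[v] + (strength[v] - w2c[v])
            size <- size + 1L
            w2c <- w2c + W[v, ]
        } else {
            v <- bestRem[order(labels[bestRem])][1]
            members[v] <- FALSE
            win <- win - w2c[v]
            wb <- wb - (strength[v] - w2c[v]) + w2c[v]
            size <- size - 1L
            w2c <- w2c - W[v, ]
        }
        current <- coh(win, wb, size)
    }
    which(members)
}

#' Grow overlapping clusters by cohesiveness
#'
#' Seed-and-grow clustering of a weighted network: seeds are taken in
#' decreasing weighted-degree order among nodes not yet covered by a
#' cluster; each seed is grown (and shrunk) greedily to a local maximum of
#' [cohesiveness()]; candidates smaller than `minSize` or with weighted
#' density below `minDensity` are discarded; highly overlapping candidates
#' (overlap score `|A∩B|²/(|A||B|) >= overlapThreshold`) are merged.
#' Cluster membership may overlap.  Ties during growth are broken by
#' lexicographic node label, so results are deterministic.
#'
#' @param network a [PPINetwork-class] object.
#' @param penalty cohesiveness penalty per member (default 2).
#' @param minSize minimum cluster size (default 3).
#' @param minDensity minimum weighted density (default 0.3).
#' @param overlapThreshold merge threshold on the overlap score
#'   (default 0.8).
#' @return a [ClusterSet-class] with p-values and hub slots unfilled
#'   (see [clusterPvalue()] and [selectClusterHubs()]); `stats$p_value`
#'   is populated by Mann-Whitney tests via [scoreClusters()].
#' @export
growClusters <- function(network, penalty = 2, minSize = 3,
                         minDensity = 0.3, overlapThreshold = 0.8) {
    g <- network@graph
    n <- igraph::vcount(g)
    if (n == 0) stop("network is empty")
    labels <- igraph::V(g)$name
    W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    diag(W) <- 0
    strength <- rowSums(W)
    covered <- logical(n)
    seedOrder <- order(-strength, labels)
    candidates <- list()
    for (s in seedOrder) {
        if (covered[s]) next
        mem <- .growFromSeed(W, strength, labels, s, penalty)
        covered[mem] <- TRUE
        candidates[[length(candidates) + 1L]] <- mem
    }
    # size / density filters
    keep <- vapply(candidates, function(mem) {
        k <- length(mem)
        if (k < minSize) return(FALSE)
        win <- sum(W[mem, mem]) / 2
        win / (k * (k - 1) / 2) >= minDensity
    }, TRUE)
    candidates <- candidates[keep]
    candidates <- unique(lapply(candidates, sort))
    # merge highly overlapping candidates (connected components of the
    # overlap graph)
    if (length(candidates) > 1) {
        m <- length(candidates)
        parent <- seq_len(m)
        find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        for (i in seq_len(m - 1)) for (j in (i + 1):m) {
            om <- length(intersect(candidates[[i]], candidates[[j]]))^2 /
                (length(candidates[[i]]) * length(candidates[[j]]))
            if (om >= overlapThreshold) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
        }
        roots <- vapply(seq_len(m), find, 1L)
        candidates <- lapply(split(seq_len(m), roots), function(idx)
            sort(unique(unlist(candidates[idx]))))
    }
    members <- lapply(candidates, function(mem) sort(labels[mem]))
    # order clusters by decreasing size then lexicographic first member
    o <- order(-vapply(members, length, 1L),
               vapply(members, `[`, "", 1L))
    members <- members[o]
    stats <- do.call(rbind, lapply(members, function(mm) {
        idx <- match(mm, labels)
        k <- length(idx)
        win <- sum(W[idx, idx]) / 2
        wext <- sum(strength[idx]) - 2 * win
        data.frame(size = k, density = win / (k * (k - 1) / 2),
                   internal_weight = win, external_weight = wext)
    }))
    if (is.null(stats))
        stats <- data.frame(size = integer(0), density = numeric(0),
                            internal_weight = numeric(0),
                            external_weight = numeric(0))
    stats <- cbind(cluster_id = as.character(seq_len(nrow(stats))), stats,
                   p_value = NA_real_, n_hubs = NA_integer_,
                   stringsAsFactors = FALSE)
    rownames(stats) <- NULL
    cs <- new("ClusterSet", members = members,
              hubs = rep(list(character(0)), length(members)),
              stats = stats,
              unclustered = sort(setdiff(labels, unlist(members))))
    scoreClusters(network, cs)
}

#' One-sided Mann-Whitney cluster quality p-value
#'
#' For each cluster member `v`, the in-weight is the total edge weight from
#' `v` to other members and the out-weight the total weight from `v` to
#' non-members.  The cluster p-value is the one-sided Mann-Whitney U test of
#' the alternative that in-weights are stochastically larger than
#' out-weights: a small p-value means the cluster is unlikely to be a random
#' fluctuation.  The exact null distribution is used when both samples have
#' at most 20 values and no ties occur; otherwise the normal approximation
#' with tie correction.
#'
#' @param network a [PPINetwork-class] object.
#' @param members character vector of cluster members (>= 2).
#' @return the one-sided p-value.
#' @export
clusterPvalue <- function(network, members) {
    members <- unique(as.character(members))
    if (length(members) < 2) stop("cluster must have >= 2 members")
    W <- igraph::as_adjacency_matrix(network@graph, attr = "weight",
                                     sparse = FALSE)
    diag(W) <- 0
    idx <- match(members, networkNodes(network))
    if (anyNA(idx)) stop("members must be network nodes")
    inw <- rowSums(W[idx, idx, drop = FALSE])
    outw <- rowSums(W[idx, -idx, drop = FALSE])
    .mannWhitneyGreater(inw, outw)
}

.mannWhitneyGreater <- function(x, y) {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) <= 20 && length(y) <= 20
    suppressWarnings(
        stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                           correct = TRUE)$p.value)
}

#' Fill cluster p-values
#'
#' @param network a [PPINetwork-class] object.
#' @param clusters a [ClusterSet-class].
#' @return the `ClusterSet` with `stats$p_value` populated.
#' @export
scoreClusters <- function(network, clusters) {
    clusters@stats$p_value <- vapply(clusters@members, function(mm)
        clusterPvalue(network, mm), 1.0)
    clusters
}

#' Weighted cluster density
#'
#' Internal weight divided by the number of member pairs,
#' `IW / (n (n - 1) / 2)`.
#'
#' @param internalWeight total weight of within-cluster edges.
#' @param size number of members (>= 2).
#' @return the weighted density.
#' @examples
#' clusterDensity(8.1, 6)   # 0.54
#' @export
clusterDensity <- function(internalWeight, size) {
    if (any(size < 2)) stop("density is undefined for singleton clusters")
    internalWeight / (size * (size - 1) / 2)
}

#' Select cluster hubs by global degree percentile
#'
#' The hub threshold is the `percentile` of the unweighted-degree
#' distribution over all network nodes (a single global threshold, not one
#' per cluster); within each cluster, members whose degree strictly exceeds
#' it become hubs.
#'
#' @param network a [PPINetwork-class] object.
#' @param clusters a [ClusterSet-class] from this network.
#' @param percentile degree percentile (default 90, i.e. top 10%).
#' @return the `ClusterSet` with `hubs` and `stats$n_hubs` filled.
#' @export
selectClusterHubs <- function(network, clusters, percentile = 90) {
    thr <- degreeThreshold(network, percentile)
    deg <- nodeDegrees(network)
    clusters@hubs <- lapply(clusters@members, function(mm)
        sort(mm[deg[mm] > thr]))
    clusters@stats$n_hubs <- vapply(clusters@hubs, length, 1L)
    clusters
}

#' @describeIn ClusterSet-class member sets (list of character vectors).
#' @param clusters,object a `ClusterSet`.
#' @export
clusterMembers <- function(clusters) clusters@members

#' @describeIn ClusterSet-class hub sets per cluster.
#' @export
clusterHubs <- function(clusters) clusters@hubs

#' @describeIn ClusterSet-class per-cluster statistics table.
#' @export
clusterStats <- function(clusters) clusters@stats

#' @describeIn ClusterSet-class nodes assigned to no cluster (the OUT
#'   group).
#' @export
unclusteredNodes <- function(clusters) clusters@unclustered

setMethod("show", "ClusterSet", function(object) {
    ns <- sum(object@stats$p_value < 0.05, na.rm = TRUE)
    cat("ClusterSet with", length(object@members), "clusters (",
        ns, "with p < 0.05 ),", length(object@unclustered),
        "unclustered nodes\n")
    if (nrow(object@stats))
        print(utils::head(object@stats, 10), digits = 4)
})

#' Write the cluster table
#'
#' TSV with one row per cluster: `cluster_id`, `size`, `density`,
#' `internal_weight`, `external_weight`, `p_value`, `n_hubs`, and
#' comma-separated `members` and `hubs` columns, followed by one `OUT` row
#' listing the unclustered nodes.
#'
#' @param clusters a [ClusterSet-class].
#' @param path output TSV path.
#' @export
writeClusters <- function(clusters, path) {
    tab <- clusters@stats
    tab$members <- vapply(clusters@members, paste, "", collapse = ",")
    tab$hubs <- vapply(clusters@hubs, paste, "", collapse = ",")
    if (length(clusters@unclustered))
        tab <- rbind(tab, data.frame(
            cluster_id = "OUT", size = length(clusters@unclustered),
            density = NA, internal_weight = NA, external_weight = NA,
            p_value = NA, n_hubs = NA,
            members = paste(clusters@unclustered, collapse = ","),
            hubs = ""))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
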