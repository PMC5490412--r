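#' Upper tail of the hypergeometric distribution
#'
#' Exact over-representation probability `P(X >= k)` for the overlap `X`
#' between a query of size `n` and an annotated set of size `K` drawn from a
#' universe of size `N`.
#'
#' @param k observed overlap count.
#' @param K annotated-set (term) size.
#' @param n query size.
#' @param N background (universe) size.
#' @return the exact tail probability.
#' @examples
#' hypergeomTail(4, 5, 4, 10)   # 5/210
#' @export
hypergeomTail <- function(k, K, n, N) {
    if (any(k < 0) || any(K < 0) || any(n < 0) ||
        any(K > N) || any(n > N) || any(k > pmin(K, n)))
        stop("hypergeometric bounds violated: need 0 <= k <= min(K, n) ",
             "and K, n <= N")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a GMT gene-set catalog
#'
#' One term per line: `term_id TAB name TAB gene TAB gene ...`.  Term
#' categories are inferred from the identifier (GO terms start with `GO:`;
#' everything else is treated as a KEGG pathway) unless given explicitly.
#'
#' @param path GMT file path.
#' @param background optional gene universe; defaults to the union of all
#'   term genes.
#' @param category optional single category (`"KEGG"` or `"GO"`) applied to
#'   every term.
#' @return an [AnnotationCatalog-class] object.
#' @export
readGmt <- function(path, background = NULL, category = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(parts, length, 1L) < 3
    if (any(short))
        stop("GMT line ", which(short)[1], " has fewer than 3 fields")
    ids <- vapply(parts, `[[`, "", 1L)
    nm <- vapply(parts, `[[`, "", 2L)
    genes <- lapply(parts, function(p) unique(p[-(1:2)]))
    cat_ <- if (is.null(category))
        ifelse(startsWith(ids, "GO:"), "GO", "KEGG")
    else rep(category, length(ids))
    annotationCatalog(ids, cat_, nm, genes, background)
}

#' Construct an annotation catalog
#'
#' @param termIds,categories,names_ parallel vectors describing the terms.
#' @param genes list of gene-symbol vectors, one per term.
#' @param background optional gene universe (default: union of term genes).
#' @return an [AnnotationCatalog-class] object.
#' @export
annotationCatalog <- function(termIds, categories, names_, genes,
                              background = NULL) {
    if (is.null(background)) background <- unique(unlist(genes))
    genes <- lapply(genes, unique)
    names(genes) <- termIds
    new("AnnotationCatalog",
        terms = data.frame(term_id = as.character(termIds),
                           category = as.character(categories),
                           name = as.character(names_),
                           stringsAsFactors = FALSE),
        genes = genes, background = unique(as.character(background)))
}

#' @describeIn AnnotationCatalog-class term metadata table.
#' @param catalog,object an `AnnotationCatalog`.
#' @export
catalogTerms <- function(catalog) catalog@terms

#' @describeIn AnnotationCatalog-class gene sets, a named list.
#' @export
catalogGenes <- function(catalog) catalog@genes

#' @describeIn AnnotationCatalog-class background gene universe.
#' @export
catalogBackground <- function(catalog) catalog@background

setMethod("show", "AnnotationCatalog", function(object) {
    tb <- table(object@terms$category)
    cat("AnnotationCatalog:", nrow(object@terms), "terms (",
        paste(names(tb), tb, collapse = ", "), "),",
        length(object@background), "background genes\n")
})

#' Hypergeometric over-representation analysis
#'
#' Tests every catalog term overlapping the query (k >= 1) with the exact
#' hypergeometric tail, adjusts p-values with Benjamini-Hochberg separately
#' within each category (KEGG pathways and GO terms are reported
#' separately), and flags significance at `alpha`.  The threshold is applied
#' to the adjusted values by default; `adjust = FALSE` applies it to the raw
#' p-values instead.
#'
#' @param query character vector of gene symbols.
#' @param catalog an [AnnotationCatalog-class].
#' @param alpha significance level in (0, 1); default 0.001.
#' @param adjust apply `alpha` to the BH-adjusted value (default) or to the
#'   raw p-value.
#' @return `data.frame` with columns `term_id`, `category`, `name`, `k`,
#'   `K`, `n`, `N`, `p`, `q`, `significant`, sorted by ascending p.
#' @export
enrichTerms <- function(query, catalog, alpha = 0.001, adjust = TRUE) {
    stopifnot(alpha > 0, alpha < 1)
    bg <- catalog@background
    query <- unique(intersect(as.character(query), bg))
    if (length(query) == 0)
        stop("query has no genes in the catalog background")
    n <- length(query)
    N <- length(bg)
    k <- vapply(catalog@genes, function(gs) length(intersect(gs, query)), 1L)
    K <- vapply(catalog@genes, length, 1L)
    res <- data.frame(term_id = catalog@terms$term_id,
                      category = catalog@terms$category,
                      name = catalog@terms$name,
                      k = unname(k), K = unname(K), n = n, N = N,
                      stringsAsFactors = FALSE)
    res <- res[res$k >= 1, , drop = FALSE]
    res$p <- hypergeomTail(res$k, res$K, res$n, res$N)
    res$q <- NA_real_
    for (cat_ in unique(res$category)) {
        sel <- res$category == cat_
        res$q[sel] <- stats::p.adjust(res$p[sel], method = "BH")
    }
    res$significant <- if (adjust) res$q < alpha else res$p < alpha
    res <- res[order(res$p, res$term_id), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Match enriched terms against a reference list
#'
#' Returns the significant enrichment rows whose term identifier appears in
#' a user-supplied reference list (e.g. pathways and terms known to be
#' related to the process under study), and their count.
#'
#' @param rows `data.frame` from [enrichTerms()].
#' @param referenceIds character vector of reference term identifiers.
#' @return list with `rows` (matched significant rows) and `count`.
#' @export
matchReference <- function(rows, referenceIds) {
    hit <- rows[rows$significant & rows$term_id %in% referenceIds, ,
                drop = FALSE]
    list(rows = hit, count = nrow(hit))
}

#' Read a reference term-id list (one id per line, '#' comments)
#'
#' @param path file path.
#' @return character vector of term ids.
#' @export
readTermList <- function(path) {
    x <- trimws(readLines(path))
    x <- sub("#.*$", "", x)
    x[nzchar(trimws(x))]
}
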