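#' Welch two-sample t-test
#'
#' Unequal-variance t-test on log2 expression values, with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.  Thin
#' wrapper over `stats::t.test(var.equal = FALSE)` that validates the
#' groups (>= 2 values, nonzero variance) with informative errors.
#'
#' @param groupA,groupB numeric vectors of log2 expression values.
#' @return list with elements `t`, `df`, `p`.
#' @export
welchT <- function(groupA, groupB) {
    check <- function(v, nm) {
        if (length(v) < 2)
            stop("group ", nm, " needs at least 2 values")
        if (!all(is.finite(v)))
            stop("group ", nm, " contains non-finite values")
        if (stats::var(v) == 0 && stats::var(c(groupA, groupB)) == 0)
            stop("group ", nm, " has zero variance")
    }
    check(groupA, "A"); check(groupB, "B")
    if (stats::var(groupA) == 0 && stats::var(groupB) == 0)
        stop("both groups have zero variance; the Welch statistic is ",
             "undefined")
    ht <- stats::t.test(groupA, groupB, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Stouffer Z-transform combination of p-values
#'
#' Converts each p-value to a standard-normal quantile
#' `Z_x = qnorm(1 - P_x)`, sums them, and divides by the square root of the
#' number of tests; the combined p-value is the upper-tail probability of
#' the result.  Used to detect a coordinated gene-set-level signal from
#' per-gene tests.
#'
#' @param pvalues numeric vector of p-values strictly inside (0, 1).
#' @return list with `z_values`, `z_combined`, `p_combined`, `n`.
#' @examples
#' stoufferCombine(c(0.05, 0.05))$p_combined   # ~0.0100
#' @export
stoufferCombine <- function(pvalues) {
    pvalues <- as.numeric(pvalues)
    if (length(pvalues) < 1) stop("need at least one p-value")
    if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues >= 1))
        stop("all p-values must lie strictly inside (0, 1)")
    z <- stats::qnorm(1 - pvalues)
    zc <- sum(z) / sqrt(length(pvalues))
    list(z_values = z, z_combined = zc,
         p_combined = stats::pnorm(zc, lower.tail = FALSE),
         n = length(pvalues))
}

#' Read a long-format expression table
#'
#' Expected columns: `gene`, `condition`, `timepoint`, `replicate`,
#' `log2_expression`.  Values are assumed already normalized (e.g. against
#' housekeeping genes) and log2 transformed.
#'
#' @param path TSV path.
#' @return the expression `data.frame`.
#' @export
readExpressionTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    needed <- c("gene", "condition", "timepoint", "replicate",
                "log2_expression")
    missing <- setdiff(needed, names(tab))
    if (length(missing))
        stop("expression table is missing column(s): ",
             paste(missing, collapse = ", "))
    if (!is.numeric(tab$log2_expression))
        stop("log2_expression must be numeric")
    tab
}

#' Per-gene Welch tests and gene-set Stouffer summary
#'
#' For every gene, compares replicate log2 expression between two
#' conditions at one timepoint with [welchT()], then combines the per-gene
#' p-values into a single coordinated-signal p-value with
#' [stoufferCombine()].
#'
#' @param table long-format expression `data.frame`
#'   (see [readExpressionTable()]).
#' @param conditionA,conditionB condition labels to compare.
#' @param timepoint timepoint to test at.
#' @return list with `per_gene` (`data.frame`: `gene`, `t`, `df`, `p`) and
#'   `summary` (the Stouffer result).
#' @export
expressionTests <- function(table, conditionA, conditionB, timepoint) {
    sub <- table[table$timepoint == timepoint, , drop = FALSE]
    genes <- sort(unique(sub$gene))
    if (length(genes) == 0) stop("no genes at timepoint ", timepoint)
    rows <- lapply(genes, function(g) {
        a <- sub$log2_expression[sub$gene == g & sub$condition == conditionA]
        b <- sub$log2_expression[sub$gene == g & sub$condition == conditionB]
        wt <- welchT(a, b)
        data.frame(gene = g, t = wt$t, df = wt$df, p = wt$p,
                   stringsAsFactors = FALSE)
    })
    perGene <- do.call(rbind, rows)
    rownames(perGene) <- NULL
    list(per_gene = perGene, summary = stoufferCombine(perGene$p))
}
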