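#' Selection frequency of genes across repetitions
#'
#' Counts, for every gene ever selected, in how many of the R repetitions
#' it appeared in the top-C set. All sets must have the same size C;
#' conservation holds exactly: the counts sum to R*C. When per-repetition
#' importance vectors are supplied, the mean importance over the
#' repetitions in which a gene was selected is attached.
#'
#' @param topSets list of R character vectors, each of size C (e.g. the
#'   `topSets` of a [NestedCvResult-class]).
#' @param importances optional list of R named numeric vectors aligned with
#'   `topSets`.
#' @return data.frame (gene_id, times_selected, frequency,
#'   mean_importance_when_selected) sorted by frequency desc, mean
#'   importance desc, gene id.
#' @export
selectionFrequency <- function(topSets, importances = NULL) {
    R <- length(topSets)
    stopifnot(R >= 1)
    C <- length(topSets[[1]])
    sizes <- lengths(topSets)
    if (any(sizes != C))
        stop("all top sets must have the same size C = ", C,
             "; got sizes ", paste(unique(sizes), collapse = ", "))
    tab <- table(unlist(topSets))
    genes <- names(tab)
    meanImp <- rep(NA_real_, length(genes))
    if (!is.null(importances)) {
        stopifnot(length(importances) == R)
        meanImp <- vapply(genes, function(g) {
            sel <- vapply(seq_len(R), function(r) g %in% topSets[[r]],
                          logical(1))
            mean(vapply(which(sel), function(r) importances[[r]][[g]],
                        numeric(1)))
        }, numeric(1))
    }
    out <- data.frame(gene_id = genes,
                      times_selected = as.integer(tab),
                      frequency = as.integer(tab) / R,
                      mean_importance_when_selected = meanImp)
    ord <- order(-out$frequency,
                 if (all(is.na(meanImp))) rep(0, nrow(out)) else -out$mean_importance_when_selected,
                 out$gene_id)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Genes selected in at least a given fraction of repetitions
#'
#' @param table a [selectionFrequency()] table.
#' @param threshold inclusive frequency threshold in (0, 1\] (default 0.70:
#'   with R = 20 repetitions this means selected at least 14 times).
#' @return character vector of gene ids, table order preserved.
#' @export
frequentGenes <- function(table, threshold = 0.70) {
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    table$gene_id[table$frequency >= threshold]
}

#' Histogram of genes by number of times selected
#'
#' @param table a [selectionFrequency()] table.
#' @param R number of repetitions.
#' @return data.frame (times_selected 1..R, n_genes).
#' @export
selectionHistogram <- function(table, R = max(table$times_selected)) {
    counts <- tabulate(table$times_selected, nbins = R)
    data.frame(times_selected = seq_len(R), n_genes = counts)
}

#' Attach differential-expression calls to a frequency table
#'
#' Joins the DE table onto the selection-frequency table and flags genes
#' selected by the multivariate procedure but not significant in the
#' univariate test.
#'
#' @param table a [selectionFrequency()] table.
#' @param deResults data.frame from [nbWaldTest()].
#' @param alpha DE significance threshold (default 0.05).
#' @return the table with extra columns lfc, adj_p, de_call
#'   ("up"/"down"/"ns").
#' @export
annotateWithDe <- function(table, deResults, alpha = 0.05) {
    i <- match(table$gene_id, deResults$gene_id)
    table$lfc <- deResults$lfc[i]
    table$adj_p <- deResults$adj_p[i]
    sig <- !is.na(table$adj_p) & table$adj_p < alpha
    table$de_call <- ifelse(!sig, "ns", ifelse(table$lfc > 0, "up", "down"))
    table
}
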