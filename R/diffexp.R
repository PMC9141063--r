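#' Benjamini-Hochberg adjustment with missing values excluded
#'
#' Wraps `stats::p.adjust(method = "BH")` so that missing p-values (genes
#' whose test did not converge) are excluded from the number of tests m and
#' returned as `NA`, per the step-up definition
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, m\,p_{(j)}/j)}.
#'
#' @param p numeric vector of p-values in \[0, 1\], `NA` allowed.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    out[ok] <- p.adjust(p[ok], method = "BH")
    out
}

# dispersion for one gene from the trend, evaluated at its mean normalized
# count; floor keeps theta = 1/alpha finite
trendDispersion <- function(meanNorm, trend) {
    pmax(trend[["a1"]] / pmax(meanNorm, 1e-8) + trend[["a0"]], 1e-8)
}

#' Per-gene negative-binomial Wald test for differential expression
#'
#' The univariate baseline: for each gene a negative-binomial generalized
#' linear model with log link and offset \eqn{\log s_i} is fitted to the
#' raw counts (pre-VST, pre-batch-correction), with design
#' `~ rin + site + sex + label` (label last). The gene-wise dispersion is
#' taken from the mean-dispersion trend (no per-gene shrinkage). The Wald
#' statistic \eqn{z = \hat\beta_{label}/se} is referred to the standard
#' normal, two-sided; the log2 fold-change is \eqn{\hat\beta_{label}/\ln 2},
#' positive meaning higher expression in cases. Non-converged fits are
#' flagged and excluded from the multiple-testing correction.
#'
#' @param se `SummarizedExperiment` with raw `counts`, or a count matrix
#'   plus `metadata`.
#' @param sizeFactors size factors; computed by [estimateSizeFactorsMoR()]
#'   if `NULL`.
#' @param design character vector of covariate columns fitted before the
#'   label (default `c("rin", "site", "sex")`); constant covariates are
#'   dropped with a warning.
#' @param dispersionTrend optional c(a0, a1); fitted if `NULL`.
#' @param metadata data.frame when `se` is a matrix.
#' @return data.frame with one row per gene: gene_id, lfc, lfc_se, p_value,
#'   adj_p, mean_norm_count, converged.
#' @export
nbWaldTest <- function(se, sizeFactors = NULL,
                       design = c("rin", "site", "sex"),
                       dispersionTrend = NULL, metadata = NULL) {
    counts <- assayCounts(se)
    md <- if (is.matrix(se)) metadata else
        as.data.frame(SummarizedExperiment::colData(se))
    if (is.null(md)) stop("metadata required")
    md$label <- checkBinaryLabels(md$label)
    if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactorsMoR(counts)
    if (!is.null(names(sizeFactors)) && !is.null(colnames(counts))) {
        if (!all(colnames(counts) %in% names(sizeFactors)))
            stop("sizeFactors missing for some samples")
        sizeFactors <- sizeFactors[colnames(counts)]
    } else if (length(sizeFactors) != ncol(counts))
        stop("sizeFactors length does not match the sample count")
    if (is.null(dispersionTrend))
        dispersionTrend <- fitDispersionTrend(counts, sizeFactors)
    usable <- design[vapply(design, function(cv)
        !is.null(md[[cv]]) && length(unique(md[[cv]])) > 1, logical(1))]
    if (!setequal(usable, design))
        warning("dropped constant/missing design covariate(s): ",
                paste(setdiff(design, usable), collapse = ", "))
    df <- md[, usable, drop = FALSE]
    if ("site" %in% usable) df$site <- droplevels(factor(df$site))
    df$label <- factor(md$label, levels = c("control", "case"))
    X <- stats::model.matrix(
        stats::reformulate(c(usable, "label")), data = df)
    off <- log(sizeFactors)
    norm <- sweep(counts, 2, sizeFactors, `/`)
    meanNorm <- rowMeans(norm)
    alpha <- trendDispersion(meanNorm, dispersionTrend)
    p <- ncol(X)
    labIdx <- p  # label is the last column by construction
    res <- matrix(NA_real_, nrow(counts), 3,
                  dimnames = list(rownames(counts), c("beta", "se", "p")))
    conv <- logical(nrow(counts))
    for (g in seq_len(nrow(counts))) {
        fam <- MASS::negative.binomial(theta = 1 / alpha[g], link = "log")
        fit <- tryCatch(
            suppressWarnings(stats::glm.fit(X, counts[g, ], family = fam,
                                            offset = off)),
            error = function(e) NULL)
        if (is.null(fit) || !fit$converged || fit$rank < p) next
        p1 <- seq_len(fit$rank)
        R <- fit$qr$qr[p1, p1, drop = FALSE]
        covBeta <- tryCatch(chol2inv(R), error = function(e) NULL)
        if (is.null(covBeta)) next
        pos <- match(labIdx, fit$qr$pivot[p1])
        seB <- sqrt(covBeta[pos, pos])
        if (!is.finite(seB) || seB <= 0) next
        b <- fit$coefficients[labIdx]
        res[g, ] <- c(b, seB, 2 * pnorm(-abs(b / seB)))
        conv[g] <- TRUE
    }
    out <- data.frame(
        gene_id = rownames(counts),
        lfc = res[, "beta"] / log(2),
        lfc_se = res[, "se"] / log(2),
        p_value = res[, "p"],
        adj_p = bhAdjust(res[, "p"]),
        mean_norm_count = meanNorm,
        converged = conv,
        row.names = rownames(counts))
    if (any(!conv))
        stageLog("nbWaldTest", "%d/%d gene(s) did not converge",
                 sum(!conv), length(conv))
    out
}

#' Significant differentially expressed genes
#'
#' Genes with BH-adjusted p-value strictly below `alpha`, partitioned by the
#' sign of the log2 fold-change (positive = up in cases).
#'
#' @param results data.frame from [nbWaldTest()].
#' @param alpha adjusted-p threshold (default 0.05, strict).
#' @return list with elements `up`, `down` (character vectors of gene ids)
#'   and `all` (their union, ordered by adjusted p).
#' @export
deGeneSet <- function(results, alpha = 0.05) {
    sig <- !is.na(results$adj_p) & results$adj_p < alpha
    up <- results$gene_id[sig & results$lfc > 0]
    down <- results$gene_id[sig & results$lfc < 0]
    ord <- order(results$adj_p[sig])
    list(up = up, down = down, all = results$gene_id[sig][ord])
}
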