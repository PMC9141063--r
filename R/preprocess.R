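#' Keep genes of allowed biotypes
#'
#' First filter of the preprocessing cascade: retain only genes whose
#' annotated biotype is in `allowed` (by default protein-coding genes and
#' long intergenic non-coding RNAs, the candidate-biomarker universe).
#'
#' @param se `SummarizedExperiment` with a `biotype` column in `rowData`,
#'   or a count matrix plus an `annotation` data.frame (gene_id, biotype).
#' @param allowed character vector of biotypes to keep.
#' @param annotation optional annotation data.frame when `se` is a matrix.
#' @return the input with non-allowed genes dropped, order preserved.
#' @export
filterBiotypes <- function(se, allowed = c("protein_coding", "lincRNA"),
                           annotation = NULL) {
    if (is.matrix(se)) {
        if (is.null(annotation)) stop("matrix input needs an annotation table")
        bt <- annotation$biotype[match(rownames(se), annotation$gene_id)]
    } else {
        bt <- SummarizedExperiment::rowData(se)$biotype
        if (is.null(bt)) stop("rowData(se) has no 'biotype' column")
    }
    miss <- rownames(se)[is.na(bt)]
    if (length(miss))
        stop("gene(s) missing from annotation: ",
             paste(head(miss, 5), collapse = ", "))
    keep <- bt %in% allowed
    stageLog("filterBiotypes", "%d -> %d genes (allowed: %s)",
             nrow(se), sum(keep), paste(allowed, collapse = ", "))
    se[keep, ]
}

#' Drop blacklisted genes
#'
#' Removes genes on a technical-variance blacklist. Blacklist ids absent
#' from the input are ignored with a warning.
#'
#' @param se `SummarizedExperiment` or count matrix.
#' @param blacklist character vector of gene ids to drop.
#' @return input minus blacklisted genes.
#' @export
dropBlacklist <- function(se, blacklist) {
    blacklist <- unique(as.character(blacklist))
    absent <- setdiff(blacklist, rownames(se))
    if (length(absent))
        warning(length(absent), " blacklist id(s) not present in the matrix")
    keep <- !(rownames(se) %in% blacklist)
    if (!any(keep)) warning("blacklist removed every gene")
    stageLog("dropBlacklist", "%d -> %d genes", nrow(se), sum(keep))
    se[keep, , drop = FALSE]
}

#' Remove lowly expressed genes by raw-count support
#'
#' A gene is retained iff strictly more than `minCount` raw counts are seen
#' in at least `ceiling(minFraction * n_samples)` samples (strict
#' inequality on the count: "more than five counts").
#'
#' @param se `SummarizedExperiment` or count matrix.
#' @param minCount count threshold (default 5, exceeded strictly).
#' @param minFraction minimum fraction of samples (default 0.10).
#' @return input minus low-expression genes.
#' @export
filterLowExpression <- function(se, minCount = 5, minFraction = 0.10) {
    counts <- assayCounts(se)
    need <- ceiling(minFraction * ncol(counts))
    keep <- rowSums(counts > minCount) >= need
    stageLog("filterLowExpression",
             "%d -> %d genes (> %d counts in >= %d samples)",
             nrow(counts), sum(keep), minCount, need)
    se[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Library-depth normalization factors: for each sample, the median over
#' reference genes of the ratio of the sample's count to the gene's
#' geometric mean across samples; reference genes are those with a strictly
#' positive geometric mean (no zero count). Factors are rescaled to
#' geometric mean 1.
#'
#' @param se `SummarizedExperiment` or count matrix.
#' @return named numeric vector of size factors (one per sample).
#' @examples
#' m <- rbind(G1 = c(10, 20), G2 = c(100, 200), G3 = c(4, 8))
#' colnames(m) <- c("a", "b")
#' sf <- estimateSizeFactorsMoR(m)
#' sf["b"] / sf["a"]   # exactly 2
#' @export
estimateSizeFactorsMoR <- function(se) {
    counts <- assayCounts(se)
    logGeo <- rowMeans(log(counts))
    ref <- is.finite(logGeo)
    if (!any(ref))
        stop("no gene with all counts > 0: cannot compute size factors")
    sf <- apply(counts[ref, , drop = FALSE], 2, function(col)
        exp(median(log(col) - logGeo[ref])))
    if (any(sf <= 0)) stop("non-positive size factor estimated")
    sf <- sf / exp(mean(log(sf)))
    setNames(sf, colnames(counts))
}

#' Independent filtering on mean normalized count
#'
#' Drops genes whose mean normalized count falls below the `meanQuantile`-th
#' quantile of that statistic across genes. The statistic ignores the
#' case/control labels, so the filter cannot bias downstream inference;
#' ties at the threshold are retained.
#'
#' @param se `SummarizedExperiment` or count matrix.
#' @param sizeFactors size factors from [estimateSizeFactorsMoR()].
#' @param meanQuantile quantile in \[0, 1); default 0.4, which removes about
#'   40% of genes on the default synthetic cohort.
#' @return input minus filtered genes.
#' @export
independentFilter <- function(se, sizeFactors, meanQuantile = 0.4) {
    if (meanQuantile < 0 || meanQuantile >= 1)
        stop("meanQuantile must lie in [0, 1)")
    counts <- assayCounts(se)
    stopifnot(ncol(counts) == length(sizeFactors))
    stat <- rowMeans(sweep(counts, 2, sizeFactors, `/`))
    keep <- stat >= quantile(stat, meanQuantile)
    stageLog("independentFilter", "%d -> %d genes (quantile %.2f)",
             nrow(counts), sum(keep), meanQuantile)
    se[keep, , drop = FALSE]
}

#' Fit the mean-dispersion trend alpha(mu) = a1/mu + a0
#'
#' Per-gene method-of-moments dispersions on normalized counts,
#' \eqn{\hat\alpha_g = \max(0, (v_g - m_g)/m_g^2)}, regressed robustly
#' (M-estimation) on \eqn{1/m_g} over genes with mean above `minMean`.
#' Negative fitted coefficients are truncated at a small positive floor
#' with a warning.
#'
#' @param se `SummarizedExperiment` or count matrix.
#' @param sizeFactors size factors.
#' @param minMean genes with mean normalized count below this are excluded
#'   from the fit (default 5, the low-expression cut).
#' @return named numeric c(a0, a1).
#' @export
fitDispersionTrend <- function(se, sizeFactors, minMean = 5) {
    counts <- assayCounts(se)
    norm <- sweep(counts, 2, sizeFactors, `/`)
    m <- rowMeans(norm)
    v <- apply(norm, 1, var)
    use <- m > minMean
    if (sum(use) < 10)
        stop("too few genes above minMean to fit the dispersion trend")
    alphaHat <- pmax(0, (v[use] - m[use]) / m[use]^2)
    inv <- 1 / m[use]
    fit <- tryCatch(MASS::rlm(alphaHat ~ inv, maxit = 50),
                    error = function(e) lm(alphaHat ~ inv))
    a <- coef(fit)
    a0 <- unname(a[1]); a1 <- unname(a[2])
    if (a0 <= 0 || a1 < 0) {
        warning("dispersion trend fit returned non-positive coefficients; ",
                "truncating")
        a0 <- max(a0, 1e-4); a1 <- max(a1, 0)
    }
    c(a0 = a0, a1 = a1)
}

# closed-form VST for the trend alpha(mu) = a1/mu + a0, applied to a
# normalized count n; monotone increasing, ~log2(n) for large n
vstClosedForm <- function(n, a0, a1) {
    log2((1 + a1 + 2 * a0 * n + 2 * sqrt(a0 * n * (1 + a1 + a0 * n))) /
         (4 * a0))
}

#' Variance stabilizing transformation
#'
#' Applies the closed-form VST for the negative-binomial dispersion trend
#' \eqn{\alpha(\mu) = a_1/\mu + a_0} to normalized counts
#' \eqn{n = k_{gi}/s_i}:
#' \deqn{v(n) = \log_2\frac{1 + a_1 + 2a_0 n +
#'   2\sqrt{a_0 n (1 + a_1 + a_0 n)}}{4 a_0}}
#' which is monotone in n and flattens the variance-mean relationship.
#' If the trend cannot be fitted with a positive asymptotic dispersion the
#' transform falls back to `log2(n + 1)` with a warning.
#'
#' @param se `SummarizedExperiment` or count matrix.
#' @param sizeFactors size factors; computed if missing.
#' @param dispersionTrend optional c(a0, a1); fitted via
#'   [fitDispersionTrend()] if `NULL`.
#' @return for a `SummarizedExperiment` input, the same object with an added
#'   assay `vst` and `metadata(se)$transformTag`; for a matrix, the
#'   transformed matrix with attributes `dispersionTrend` and `transformTag`.
#' @export
vstTransform <- function(se, sizeFactors = NULL, dispersionTrend = NULL) {
    counts <- assayCounts(se)
    if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactorsMoR(counts)
    norm <- sweep(counts, 2, sizeFactors, `/`)
    if (is.null(dispersionTrend))
        dispersionTrend <- tryCatch(fitDispersionTrend(counts, sizeFactors),
                                    error = function(e) c(a0 = -1, a1 = 0))
    a0 <- dispersionTrend[["a0"]]; a1 <- dispersionTrend[["a1"]]
    if (is.na(a0) || a0 <= 0 || a1 < 0) {
        warning("no valid dispersion trend; falling back to log2(n + 1)")
        v <- log2(norm + 1)
        tag <- "log2norm+1"
    } else {
        v <- vstClosedForm(norm, a0, a1)
        tag <- sprintf("vst(a0=%.4g,a1=%.4g)", a0, a1)
    }
    if (is(se, "SummarizedExperiment")) {
        SummarizedExperiment::assay(se, "vst", withDimnames = FALSE) <- v
        S4Vectors::metadata(se)$transformTag <- tag
        S4Vectors::metadata(se)$dispersionTrend <- dispersionTrend
        S4Vectors::metadata(se)$sizeFactors <- sizeFactors
        se
    } else {
        attr(v, "dispersionTrend") <- dispersionTrend
        attr(v, "transformTag") <- tag
        v
    }
}

controlsPerSite <- function(metadata) {
    tab <- table(site = as.character(metadata$site),
                 label = factor(metadata$label, c("case", "control")))
    setNames(as.numeric(tab[, "control"]), rownames(tab))
}

#' Exclude samples from sites with too few controls
#'
#' Control-anchored batch removal needs at least two control samples per
#' site; all samples (cases and controls) from sites falling short are
#' removed, with per-site removal counts logged.
#'
#' @param se `SummarizedExperiment` with `site` and `label` in `colData`,
#'   or a matrix plus `metadata` data.frame.
#' @param minControls minimum controls a site must have (default 2).
#' @param metadata data.frame when `se` is a matrix.
#' @return input minus samples from small sites.
#' @export
excludeSmallSites <- function(se, minControls = 2, metadata = NULL) {
    md <- if (is.matrix(se)) metadata else
        as.data.frame(SummarizedExperiment::colData(se))
    if (is.null(md$site) || is.null(md$label))
        stop("metadata must carry 'site' and 'label'")
    ctrl <- controlsPerSite(md)
    bad <- names(ctrl)[ctrl < minControls]
    drop <- as.character(md$site) %in% bad
    if (all(drop)) stop("all sites have < ", minControls, " controls")
    for (s in bad)
        stageLog("excludeSmallSites", "site %s: %d sample(s) removed (%d control(s))",
                 s, sum(md$site == s), ctrl[s])
    stageLog("excludeSmallSites", "%d -> %d samples", nrow(md), sum(!drop))
    if (is.matrix(se))
        list(counts = se[, !drop, drop = FALSE],
             metadata = md[!drop, , drop = FALSE])
    else {
        out <- se[, !drop]
        if (is.factor(out$site)) out$site <- droplevels(out$site)
        out
    }
}

# least-squares multi-response fit: Y genes x samples, X samples x p.
# returns p x genes coefficient matrix
lsCoef <- function(X, Y) {
    qr.coef(qr(X), t(Y))
}

#' Remove per-site batch effects anchored on control samples
#'
#' For each gene, the site offset is estimated from control samples only as
#' the deviation of the site's control mean from the global control mean
#' (centred so offsets sum to zero across sites), and subtracted from every
#' sample of that site. The correction is cross-fitted and noise-matched:
#' every sample's offset is computed from n_c - 1 of the site's n_c
#' controls — a control always excludes itself, and a case excludes one
#' control chosen round-robin. Naively subtracting the full-control-mean
#' offset from everyone (the textbook anchored correction) leaves a
#' class-asymmetric second-moment imprint of the labels: control variance
#' is shrunk by (1 - 1/n_c) while case variance is inflated by (1 + 1/n_c),
#' which a downstream classifier can exploit even on null data. With the
#' jackknife-matched form, corrected case and control values have identical
#' sampling distributions under the null (both carry independent offset
#' noise of variance sigma^2/(n_c - 1)).
#'
#' Planted noiseless offsets are recovered exactly, and in the noiseless
#' case per-site control means of each gene are exactly equalized.
#'
#' @param expr expression matrix (genes x samples) or a
#'   `SummarizedExperiment` with a `vst` (or sole) assay.
#' @param metadata data.frame with `site` and `label` when `expr` is a
#'   matrix.
#' @return corrected matrix (attribute `siteOffsets`: sites x genes), or the
#'   `SummarizedExperiment` with assay `corrected` added.
#' @export
removeSiteBatch <- function(expr, metadata = NULL) {
    isSE <- is(expr, "SummarizedExperiment")
    if (isSE) {
        md <- as.data.frame(SummarizedExperiment::colData(expr))
        an <- SummarizedExperiment::assayNames(expr)
        mat <- SummarizedExperiment::assay(
            expr, if ("vst" %in% an) "vst" else 1L)
    } else { md <- metadata; mat <- expr }
    site <- droplevels(factor(md$site))
    isCtrl <- md$label == "control"
    ctrl <- controlsPerSite(md)
    if (any(ctrl == 0))
        stop("site(s) without control samples: ",
             paste(names(ctrl)[ctrl == 0], collapse = ", "),
             "; run excludeSmallSites() first")
    if (any(ctrl == 1))
        warning("site(s) with a single control: no leave-one-out offset ",
                "possible there; consider excludeSmallSites()")
    gm <- rowMeans(mat[, isCtrl, drop = FALSE])
    raw <- vapply(levels(site), function(s)
        rowMeans(mat[, isCtrl & site == s, drop = FALSE]) - gm,
        numeric(nrow(mat)))                     # genes x sites
    offsets <- t(raw - rowMeans(raw))           # sites x genes, sum-to-zero
    centre <- rowMeans(raw)                     # shared shift, per gene
    corrected <- mat
    for (s in levels(site)) {
        inS <- site == s
        cIdx <- which(inS & isCtrl)
        caseIdx <- which(inS & !isCtrl)
        n <- length(cIdx)
        if (n >= 2) {
            S <- rowSums(mat[, cIdx, drop = FALSE])
            # controls: leave-own-sample-out offset
            loo <- (S - mat[, cIdx, drop = FALSE]) / (n - 1) - gm - centre
            corrected[, cIdx] <- mat[, cIdx, drop = FALSE] - loo
            # cases: exclude one control round-robin so the offset noise
            # matches the controls' (n - 1 anchors for every sample)
            for (k in seq_along(caseIdx)) {
                excl <- cIdx[(k - 1L) %% n + 1L]
                off <- (S - mat[, excl]) / (n - 1) - gm - centre
                corrected[, caseIdx[k]] <- mat[, caseIdx[k]] - off
            }
        } else {
            corrected[, c(cIdx, caseIdx)] <-
                mat[, c(cIdx, caseIdx), drop = FALSE] - (raw[, s] - centre)
        }
    }
    if (isSE) {
        SummarizedExperiment::assay(expr, "corrected",
                                    withDimnames = FALSE) <- corrected
        S4Vectors::metadata(expr)$siteOffsets <- offsets
        S4Vectors::metadata(expr)$transformTag <-
            paste0(S4Vectors::metadata(expr)$transformTag, "+site-removed")
        expr
    } else {
        attr(corrected, "siteOffsets") <- offsets
        corrected
    }
}

#' Residualize technical covariates out of an expression matrix
#'
#' Per gene, least-squares coefficients for the covariates (default sex and
#' RIN, fitted on all samples with the disease label deliberately absent
#' from the model) are estimated and the covariate contribution is
#' subtracted; the intercept is retained. Constant covariates are skipped
#' with a warning.
#'
#' @param expr genes x samples matrix or `SummarizedExperiment` (uses the
#'   `corrected` assay if present, else `vst`, else the first).
#' @param covariates character vector of `colData`/metadata columns.
#' @param metadata data.frame when `expr` is a matrix.
#' @return residualized matrix, or the `SummarizedExperiment` with the
#'   working assay replaced by its residualized version.
#' @export
removeCovariates <- function(expr, covariates = c("sex", "rin"),
                             metadata = NULL) {
    isSE <- is(expr, "SummarizedExperiment")
    if (isSE) {
        md <- as.data.frame(SummarizedExperiment::colData(expr))
        an <- SummarizedExperiment::assayNames(expr)
        use <- if ("corrected" %in% an) "corrected"
               else if ("vst" %in% an) "vst" else an[1]
        mat <- SummarizedExperiment::assay(expr, use)
    } else { md <- metadata; mat <- expr }
    keep <- character()
    for (cv in covariates) {
        x <- md[[cv]]
        if (is.null(x)) stop("covariate '", cv, "' missing from metadata")
        if (any(!is.finite(as.numeric(factor(x)))))
            stop("covariate '", cv, "' has missing values")
        if (length(unique(x)) < 2) {
            warning("covariate '", cv, "' is constant; skipped")
            next
        }
        keep <- c(keep, cv)
    }
    if (!length(keep)) return(expr)
    X <- stats::model.matrix(
        stats::reformulate(keep), data = md)
    beta <- lsCoef(X, mat)
    fittedCov <- X[, -1, drop = FALSE] %*% beta[-1, , drop = FALSE]
    corrected <- mat - t(fittedCov)
    if (isSE) {
        SummarizedExperiment::assay(expr, use, withDimnames = FALSE) <- corrected
        S4Vectors::metadata(expr)$transformTag <-
            paste0(S4Vectors::metadata(expr)$transformTag, "+",
                   paste(keep, collapse = "/"), "-removed")
        expr
    } else corrected
}

#' Run the full preprocessing cascade
#'
#' Fixed-order cascade turning raw counts into a classifier-ready
#' expression matrix: biotype filter, blacklist, low-expression filter,
#' median-of-ratios size factors, independent filtering, variance
#' stabilizing transformation, small-site exclusion, control-anchored
#' site-batch removal, sex/RIN residualization. Each stage logs its
#' input/output gene and sample counts; the returned object records the
#' per-stage accounting in `metadata(se)$preprocessReport`.
#'
#' @param se `SummarizedExperiment` with assay `counts`, `rowData$biotype`,
#'   and `colData` label/site/sex/rin.
#' @param blacklist optional character vector of gene ids to drop.
#' @param allowedBiotypes biotypes retained (default protein_coding,
#'   lincRNA).
#' @param minCount,minFraction low-expression filter parameters.
#' @param meanQuantile independent-filtering quantile.
#' @param minControls minimum controls per site.
#' @param covariates covariates to residualize after batch removal.
#' @return `SummarizedExperiment` with assays counts/vst/corrected on the
#'   retained genes and samples, plus report metadata.
#' @examples
#' se <- simulateCohort(simConfig(nCases = 60, nControls = 40, nGenes = 300,
#'                                nSites = 4, nInformative = 10,
#'                                fracSmallSites = 0, seed = 3))
#' pp <- suppressMessages(preprocessCounts(se))
#' SummarizedExperiment::assayNames(pp)
#' @export
preprocessCounts <- function(se, blacklist = NULL,
                             allowedBiotypes = c("protein_coding", "lincRNA"),
                             minCount = 5, minFraction = 0.10,
                             meanQuantile = 0.4, minControls = 2,
                             covariates = c("sex", "rin")) {
    report <- list(input = dim(se))
    se <- filterBiotypes(se, allowedBiotypes)
    report$afterBiotype <- nrow(se)
    if (!is.null(blacklist) && length(blacklist)) {
        se <- dropBlacklist(se, blacklist)
        report$afterBlacklist <- nrow(se)
    }
    se <- filterLowExpression(se, minCount, minFraction)
    report$afterLowExpression <- nrow(se)
    sf <- estimateSizeFactorsMoR(se)
    se <- independentFilter(se, sf, meanQuantile)
    report$afterIndependentFilter <- nrow(se)
    se <- vstTransform(se, sf)
    se <- excludeSmallSites(se, minControls)
    report$afterSiteExclusion <- ncol(se)
    S4Vectors::metadata(se)$sizeFactors <- sf[colnames(se)]
    se <- removeSiteBatch(se)
    se <- removeCovariates(se, covariates)
    report$sizeFactors <- sf[colnames(se)]
    report$dispersionTrend <- S4Vectors::metadata(se)$dispersionTrend
    report$transformTag <- S4Vectors::metadata(se)$transformTag
    S4Vectors::metadata(se)$preprocessReport <- report
    se
}

#' Classifier-ready expression matrix of a preprocessed cohort
#'
#' @param se output of [preprocessCounts()].
#' @return genes x samples numeric matrix (the `corrected` assay).
#' @export
correctedExpr <- function(se) {
    an <- SummarizedExperiment::assayNames(se)
    if (!"corrected" %in% an) stop("no 'corrected' assay: run preprocessCounts()")
    SummarizedExperiment::assay(se, "corrected")
}
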