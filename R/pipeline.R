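# Plain-text IO: counts/expression as TSV (gene rows, sample columns),
# metadata/annotation as TSV, truth/config/manifest as JSON.

#' Read a gene x sample count matrix from TSV
#'
#' @param path TSV with gene ids in the first column and a header row of
#'   sample ids.
#' @return integer matrix with dimnames.
#' @export
readCountsTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
    storage.mode(m) <- "integer"
    m
}

#' Write a gene x sample matrix as TSV
#'
#' @param mat matrix with dimnames.
#' @param path output path.
#' @export
writeMatrixTsv <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Assemble a SummarizedExperiment cohort from plain-text inputs
#'
#' @param countsPath counts TSV ([readCountsTsv()] layout).
#' @param metadataPath sample metadata TSV (column `sample_id` plus label,
#'   site, sex, rin, ...).
#' @param annotationPath gene annotation TSV (gene_id, symbol, biotype).
#' @return `SummarizedExperiment` ready for [preprocessCounts()].
#' @export
readCohort <- function(countsPath, metadataPath, annotationPath) {
    for (p in c(countsPath, metadataPath, annotationPath))
        if (!file.exists(p)) stop("missing input file: ", p)
    counts <- readCountsTsv(countsPath)
    md <- read.delim(metadataPath)
    rownames(md) <- md$sample_id
    an <- read.delim(annotationPath)
    rownames(an) <- an$gene_id
    if (!all(colnames(counts) %in% rownames(md)))
        stop("metadata missing samples present in the count matrix")
    if (!all(rownames(counts) %in% rownames(an)))
        stop("annotation missing genes present in the count matrix")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(an[rownames(counts), , drop = FALSE]),
        colData = S4Vectors::DataFrame(md[colnames(counts), , drop = FALSE]))
}

#' Run the full workflow end to end
#'
#' Orchestrates preprocess, differential expression, nested
#' cross-validation, stability and endophenotype evaluation on a cohort,
#' writing every stage's table plus a manifest to `outdir`. A single
#' master seed fans out deterministically to every stochastic stage
#' (stage-name-keyed derivation), so reruns with the same inputs and seed
#' reproduce all outputs bit-identically.
#'
#' @param se cohort `SummarizedExperiment` (e.g. from [simulateCohort()] or
#'   [readCohort()]).
#' @param outdir output directory (created if needed).
#' @param cGrid feature-set sizes swept; default a geometric-ish grid
#'   scaled to the post-filter gene count.
#' @param rfCfg,boostPar,k,nRep learning-stage settings (see
#'   [runNestedCv()]).
#' @param alpha DE significance threshold.
#' @param stabilityThreshold frequency cut for the reported signature
#'   (default 0.70).
#' @param blacklist optional gene-id blacklist.
#' @param endophenotypes metadata columns compared via
#'   [endophenotypeTest()].
#' @param seed master seed.
#' @return (invisibly) list with the preprocessed cohort, DE table, the
#'   [NestedCvResult-class], frequency table and endophenotype results.
#' @export
runPipeline <- function(se, outdir, cGrid = NULL,
                        rfCfg = rfConfig(), boostPar = boostParams(),
                        k = 10, nRep = 20, alpha = 0.05,
                        stabilityThreshold = 0.70, blacklist = NULL,
                        endophenotypes = c("moca_class", "rbd",
                                           "motor_class", "smell_class",
                                           "age_class"),
                        seed = 1) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    t0 <- Sys.time()
    pp <- preprocessCounts(se, blacklist = blacklist)
    expr <- correctedExpr(pp)
    md <- as.data.frame(SummarizedExperiment::colData(pp))
    if (is.null(cGrid)) {
        f <- nrow(expr)
        cGrid <- unique(pmin(c(5, 10, 20, 40, 80, 160, 320, 640, f), f))
        cGrid <- cGrid[cGrid >= 1]
    }

    de <- nbWaldTest(pp, sizeFactors = S4Vectors::metadata(pp)$sizeFactors,
                     dispersionTrend = S4Vectors::metadata(pp)$dispersionTrend)
    deTab <- de[order(de$adj_p), ]
    write.table(deTab, file.path(outdir, "diffexp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    cv <- runNestedCv(expr, md$label, cGrid, rfCfg, boostPar, k = k,
                      nRep = nRep, seed = deriveSeed(seed, "nestedcv"))
    write.table(cvPredictions(cv), file.path(outdir, "predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    curve <- cvCurve(cv)
    curveTab <- data.frame(C = curve@grid, median_auc = curve@medianAuc,
                           mad_auc = curve@madAuc)
    write.table(curveTab, file.path(outdir, "auc_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(grid = curve@grid, median = curve@medianAuc,
                              mad = curve@madAuc, c_star = curve@cStar),
                         file.path(outdir, "auc_curve.json"),
                         auto_unbox = TRUE, digits = NA)

    freq <- selectionFrequency(cv@topSets)
    freq <- annotateWithDe(freq, deTab, alpha)
    write.table(freq, file.path(outdir, "selection_frequency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(selectionHistogram(freq, nRep),
                file.path(outdir, "selection_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    signature <- frequentGenes(freq, stabilityThreshold)
    writeLines(signature, file.path(outdir, "signature.txt"))

    metrics <- confusionMetrics(
        cvPredictions(cv)$true_label[cvPredictions(cv)$C == curve@cStar],
        cvPredictions(cv)$predicted_probability[cvPredictions(cv)$C == curve@cStar])
    endo <- lapply(endophenotypes, function(ep)
        tryCatch(endophenotypeTest(cvPredictions(cv), md, ep, C = curve@cStar),
                 error = function(e) list(grouping = ep,
                                          error = conditionMessage(e))))
    db <- tryCatch(
        deBaseline(SummarizedExperiment::assay(pp, "counts"), expr, md,
                   alpha = alpha, boostPar = boostPar,
                   splitSeed = deriveSeed(seed, "debaseline")),
        error = function(e) list(auc = NA_real_,
                                 error = conditionMessage(e)))

    manifest <- list(
        seed = seed, k = k, nRep = nRep, cGrid = cGrid, alpha = alpha,
        stabilityThreshold = stabilityThreshold,
        rfConfig = unclass(rfCfg), boostParams = unclass(boostPar),
        dims = list(genes = nrow(expr), samples = ncol(expr)),
        preprocessReport = lapply(
            S4Vectors::metadata(pp)$preprocessReport,
            function(x) if (is.numeric(x)) unname(x) else x),
        cStar = curve@cStar,
        maxMedianAuc = max(curve@medianAuc),
        deBaselineAuc = db$auc,
        metricsAtCstar = as.list(metrics$metrics),
        endophenotypes = endo,
        elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    invisible(list(preprocessed = pp, de = deTab, cv = cv, frequency = freq,
                   signature = signature, endophenotypes = endo,
                   deBaseline = db, manifest = manifest))
}
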