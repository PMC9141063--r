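#' Gradient-boosting parameters
#'
#' Defaults follow the library's long-standing binary-classification
#' defaults (no tuning): 100 boosting rounds, depth-6 trees, learning rate
#' 0.3, logistic objective.
#'
#' @param nRounds boosting rounds.
#' @param maxDepth maximum tree depth.
#' @param learningRate shrinkage (eta).
#' @param ... further `xgboost` parameters passed through.
#' @return list of class `BoostParams`.
#' @export
boostParams <- function(nRounds = 100, maxDepth = 6, learningRate = 0.3,
                        ...) {
    structure(list(nRounds = nRounds, maxDepth = maxDepth,
                   learningRate = learningRate, extra = list(...)),
              class = "BoostParams")
}

# fit + predict wrappers around xgboost; x is samples x features
fitBoost <- function(x, y01, params) {
    dtr <- xgboost::xgb.DMatrix(as.matrix(x), label = y01)
    pl <- c(list(objective = "binary:logistic",
                 max_depth = params$maxDepth, eta = params$learningRate,
                 nthread = 1), params$extra)
    xgboost::xgb.train(params = pl, data = dtr, nrounds = params$nRounds,
                       verbose = 0)
}

predictBoost <- function(model, x) {
    as.numeric(predict(model, xgboost::xgb.DMatrix(as.matrix(x))))
}

#' Stratified k-fold assignment
#'
#' Partitions samples into k folds with per-fold class counts within one
#' sample of the global class ratio: within each class, the shuffled
#' samples are dealt round-robin over the folds.
#'
#' @param labels "case"/"control" per sample.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return integer fold id (1..k) per sample.
#' @export
makeFolds <- function(labels, k = 10, seed = 1) {
    labels <- checkBinaryLabels(labels)
    tab <- table(labels)
    if (any(tab < k))
        stop("class '", names(tab)[which.min(tab)], "' has fewer than k = ",
             k, " members")
    fold <- integer(length(labels))
    withSeed(seed, {
        for (cl in names(tab)) {
            idx <- sample(which(labels == cl))
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    fold
}

#' Rank on a training fold and classify its validation fold over a C sweep
#'
#' One inner cell of the nested scheme: the repeated-forest ranking is
#' computed from the training portion only, then for each C in the grid a
#' gradient-boosted model is trained on the top-C training features and
#' predicted case probabilities are emitted for the validation samples.
#' Any overlap between training and validation indices is a hard error
#' (leakage guard).
#'
#' @param expr genes x samples expression matrix (full cohort).
#' @param labels "case"/"control" per sample.
#' @param trainIdx,valIdx disjoint sample index vectors.
#' @param cGrid strictly increasing feature-set sizes, max <= nrow(expr).
#' @param rfCfg an [rfConfig()].
#' @param boostPar a [boostParams()].
#' @param rankSeed seed for the forest repetitions of this fold.
#' @return list with `ranking` (a [RankedFeatures-class]) and `records`
#'   (data.frame: sample_id, C, predicted_probability, true_label).
#' @export
runFold <- function(expr, labels, trainIdx, valIdx, cGrid,
                    rfCfg = rfConfig(), boostPar = boostParams(),
                    rankSeed = 1) {
    if (length(intersect(trainIdx, valIdx)))
        stop("leakage: training and validation folds overlap")
    if (is.unsorted(cGrid, strictly = TRUE) || max(cGrid) > nrow(expr) ||
        min(cGrid) < 1)
        stop("cGrid must be strictly increasing within [1, f]")
    labels <- checkBinaryLabels(labels)
    ranking <- rankGenes(expr[, trainIdx, drop = FALSE], labels[trainIdx],
                         rfCfg, baseSeed = rankSeed)
    recs <- lapply(cGrid, function(C) {
        genes <- topC(ranking, C)
        model <- fitBoost(t(expr[genes, trainIdx, drop = FALSE]),
                          as.integer(labels[trainIdx] == "case"), boostPar)
        prob <- predictBoost(model, t(expr[genes, valIdx, drop = FALSE]))
        data.frame(sample_id = colnames(expr)[valIdx], C = C,
                   predicted_probability = prob,
                   true_label = labels[valIdx])
    })
    list(ranking = ranking, records = do.call(rbind, recs))
}

#' Repeated stratified nested cross-validation with a top-C sweep
#'
#' The outer evaluation engine: `nRep` repetitions of stratified `k`-fold
#' cross-validation. In every training fold the repeated-forest importance
#' ranking is recomputed (so feature selection never sees validation data)
#' and gradient-boosted classifiers over the `cGrid` sweep are evaluated on
#' the held-out fold. Validation predictions are pooled across the k folds
#' of a repetition to give one AUC-versus-C curve per repetition; curves
#' are aggregated into their pointwise median and mean absolute deviation,
#' and `cStar` is the grid argmax of the median (smallest C on ties).
#'
#' Each repetition also contributes one top-`cStar` gene set (from the
#' importance averaged over that repetition's k fold rankings), the input
#' to [selectionFrequency()].
#'
#' @inheritParams runFold
#' @param k folds per repetition (default 10).
#' @param nRep repetitions (default 20).
#' @param seed master seed; folds and forests derive their streams from it.
#' @return a [NestedCvResult-class].
#' @export
runNestedCv <- function(expr, labels, cGrid, rfCfg = rfConfig(),
                        boostPar = boostParams(), k = 10, nRep = 20,
                        seed = 1) {
    labels <- checkBinaryLabels(labels)
    stopifnot(ncol(expr) == length(labels))
    allRecords <- list(); rankings <- list(); repMeanImp <- list()
    for (r in seq_len(nRep)) {
        fold <- makeFolds(labels, k, seed = deriveSeed(seed, "folds", r))
        impSum <- NULL
        for (f in seq_len(k)) {
            valIdx <- which(fold == f)
            trainIdx <- which(fold != f)
            res <- runFold(expr, labels, trainIdx, valIdx, cGrid, rfCfg,
                           boostPar,
                           rankSeed = deriveSeed(seed, "rank", r, f))
            res$records$repetition <- r
            res$records$fold <- f
            allRecords[[length(allRecords) + 1L]] <- res$records
            rankings[[sprintf("rep%d_fold%d", r, f)]] <- res$ranking
            imp <- meanImportance(res$ranking)[rownames(expr)]
            impSum <- if (is.null(impSum)) imp else impSum + imp
        }
        repMeanImp[[r]] <- impSum / k
    }
    predictions <- do.call(rbind, allRecords)
    rownames(predictions) <- NULL
    curve <- aggregateCurve(predictions, cGrid)
    topSets <- lapply(repMeanImp, function(imp) {
        ord <- order(-imp, names(imp))
        names(imp)[ord][seq_len(curve@cStar)]
    })
    new("NestedCvResult", predictions = predictions, rankings = rankings,
        curve = curve, topSets = topSets,
        config = list(cGrid = cGrid, k = k, nRep = nRep, seed = seed,
                      rfConfig = unclass(rfCfg),
                      boostParams = unclass(boostPar)))
}

#' Aggregate prediction records into an AUC-versus-C curve
#'
#' Per repetition and per C, validation predictions pooled across the k
#' folds are reduced to one AUC by [rocAuc()]; the curve statistics are the
#' pointwise median and mean absolute deviation about the median over
#' repetitions, and `cStar` is the smallest grid C attaining the maximal
#' median. A missing (repetition, C) cell or a sample predicted more than
#' once per (repetition, C) is an error.
#'
#' @param predictions prediction-record data.frame (sample_id, repetition,
#'   C, predicted_probability, true_label).
#' @param grid the C grid the records must cover.
#' @return an [AucCurve-class].
#' @export
aggregateCurve <- function(predictions, grid) {
    reps <- sort(unique(predictions$repetition))
    auc <- matrix(NA_real_, length(reps), length(grid),
                  dimnames = list(reps, grid))
    for (i in seq_along(reps)) for (j in seq_along(grid)) {
        rec <- predictions[predictions$repetition == reps[i] &
                           predictions$C == grid[j], ]
        if (!nrow(rec))
            stop("missing cell: repetition ", reps[i], ", C = ", grid[j])
        if (anyDuplicated(rec$sample_id))
            stop("sample predicted more than once in repetition ", reps[i],
                 " at C = ", grid[j])
        auc[i, j] <- rocAuc(rec$true_label, rec$predicted_probability)
    }
    med <- apply(auc, 2, median)
    mad <- vapply(seq_along(grid),
                  function(j) mean(abs(auc[, j] - med[j])), numeric(1))
    new("AucCurve", grid = as.numeric(grid), aucByRep = auc,
        medianAuc = as.numeric(med), madAuc = mad,
        cStar = as.numeric(grid[which.max(med)]))
}

#' Linearly interpolate the median AUC curve between grid points
#'
#' @param curve an [AucCurve-class].
#' @param cOut C values to interpolate at (within the grid span).
#' @return data.frame with columns C, median_auc, mad_auc.
#' @export
interpolateCurve <- function(curve, cOut) {
    stopifnot(is(curve, "AucCurve"))
    if (any(cOut < min(curve@grid) | cOut > max(curve@grid)))
        stop("cOut outside the grid span")
    data.frame(
        C = cOut,
        median_auc = approx(curve@grid, curve@medianAuc, cOut)$y,
        mad_auc = approx(curve@grid, curve@madAuc, cOut)$y)
}

#' Differential-expression baseline classifier
#'
#' The univariate comparison experiment: one stratified 90/10 split; genes
#' called differentially expressed (BH-adjusted p < `alpha`) feed a
#' gradient-boosted classifier; the held-out AUC is returned. By default
#' the DE genes are computed on the training portion only (leakage-safe);
#' `leakageSafe = FALSE` computes them on all samples, and a precomputed
#' gene set can be supplied via `deGenes`.
#'
#' @param counts raw genes x samples count matrix (pre-VST), aligned with
#'   `expr` columns.
#' @param expr preprocessed genes x samples expression matrix the
#'   classifier consumes.
#' @param metadata data.frame with label (and design covariates) per sample.
#' @param alpha DE significance threshold (default 0.05).
#' @param boostPar a [boostParams()].
#' @param splitSeed seed of the 90/10 split.
#' @param deGenes optional precomputed DE gene ids (skips the test).
#' @param leakageSafe compute DE genes on the training split only (default
#'   TRUE).
#' @param design design covariates passed to [nbWaldTest()].
#' @return list with `auc`, `deGenes`, `testIdx`.
#' @export
deBaseline <- function(counts, expr, metadata, alpha = 0.05,
                       boostPar = boostParams(), splitSeed = 1,
                       deGenes = NULL, leakageSafe = TRUE,
                       design = c("rin", "site", "sex")) {
    labels <- checkBinaryLabels(metadata$label)
    fold <- makeFolds(labels, k = 10, seed = splitSeed)
    testIdx <- which(fold == 1L)
    trainIdx <- which(fold != 1L)
    if (is.null(deGenes)) {
        idx <- if (leakageSafe) trainIdx else seq_along(labels)
        de <- nbWaldTest(counts[, idx, drop = FALSE],
                         metadata = metadata[idx, , drop = FALSE],
                         design = design)
        deGenes <- deGeneSet(de, alpha)$all
    }
    deGenes <- intersect(deGenes, rownames(expr))
    if (!length(deGenes)) stop("empty DE gene set")
    model <- fitBoost(t(expr[deGenes, trainIdx, drop = FALSE]),
                      as.integer(labels[trainIdx] == "case"), boostPar)
    prob <- predictBoost(model, t(expr[deGenes, testIdx, drop = FALSE]))
    list(auc = rocAuc(labels[testIdx], prob), deGenes = deGenes,
         testIdx = testIdx)
}
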