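#' Random-forest configuration for the importance-ranking stage
#'
#' @param nTrees trees per forest (default 1000).
#' @param featuresPerSplit `"sqrt"` (the forest default, \eqn{\sqrt f}
#'   features tried at each split) or an explicit count.
#' @param nRepetitions forests grown per training fold, each with its own
#'   seed (default 100).
#' @param importanceMode `"impurity"` (mean decrease in Gini, default) or
#'   `"permutation"`.
#' @param baseSeed seed of the first repetition; repetition b uses
#'   `baseSeed + b - 1`.
#' @return validated list of class `RfConfig`.
#' @export
rfConfig <- function(nTrees = 1000, featuresPerSplit = "sqrt",
                     nRepetitions = 100,
                     importanceMode = c("impurity", "permutation"),
                     baseSeed = 1) {
    importanceMode <- match.arg(importanceMode)
    stopifnot(nTrees >= 1, nRepetitions >= 1)
    if (!identical(featuresPerSplit, "sqrt"))
        stopifnot(is.numeric(featuresPerSplit), featuresPerSplit >= 1)
    structure(list(nTrees = nTrees, featuresPerSplit = featuresPerSplit,
                   nRepetitions = nRepetitions,
                   importanceMode = importanceMode, baseSeed = baseSeed),
              class = "RfConfig")
}

resolveMtry <- function(featuresPerSplit, f) {
    m <- if (identical(featuresPerSplit, "sqrt")) floor(sqrt(f))
         else as.integer(featuresPerSplit)
    max(1L, min(m, f))
}

#' Random-forest gene importances on a training set
#'
#' Grows one seeded forest on the training samples and returns the per-gene
#' importance (mean decrease in impurity, or permutation importance). The
#' caller must pass training samples only; validation data must never reach
#' this function.
#'
#' @param exprTrain genes x samples expression matrix (training portion).
#' @param labelsTrain "case"/"control" per training sample.
#' @param config an [rfConfig()].
#' @param repSeed seed of this repetition.
#' @return named numeric importance vector over the genes of `exprTrain`.
#' @export
rfImportance <- function(exprTrain, labelsTrain, config = rfConfig(),
                         repSeed = config$baseSeed) {
    labelsTrain <- checkBinaryLabels(labelsTrain)
    if (length(unique(labelsTrain)) < 2)
        stop("training labels contain a single class")
    stopifnot(ncol(exprTrain) == length(labelsTrain))
    x <- t(exprTrain)
    colnames(x) <- rownames(exprTrain)
    fit <- ranger::ranger(
        x = x, y = factor(labelsTrain, c("control", "case")),
        num.trees = config$nTrees,
        mtry = resolveMtry(config$featuresPerSplit, nrow(exprTrain)),
        importance = config$importanceMode,
        seed = repSeed, num.threads = 1, verbose = FALSE)
    imp <- fit$variable.importance[rownames(exprTrain)]
    setNames(as.numeric(imp), rownames(exprTrain))
}

#' Average importance vectors and rank genes
#'
#' Element-wise mean of aligned importance vectors, sorted non-increasing;
#' ties are broken by lexicographic gene id so the ranking is deterministic.
#'
#' @param importances list of named numeric vectors over the same genes.
#' @param source optional fingerprint of the training data.
#' @return a [RankedFeatures-class].
#' @export
averageRank <- function(importances, source = "") {
    stopifnot(length(importances) >= 1)
    ids <- names(importances[[1]])
    for (v in importances)
        if (!identical(names(v), ids))
            stop("importance vectors are not aligned on the same gene order")
    m <- colMeans(do.call(rbind, importances))
    ord <- order(-m, ids)
    new("RankedFeatures", geneIds = ids[ord], meanImportance = m[ord],
        nRepetitions = length(importances), source = source)
}

#' Top-C genes of a ranking
#'
#' @param ranked a [RankedFeatures-class].
#' @param C number of genes to take (1..f); prefixes are nested:
#'   `topC(r, 10)` is always a prefix of `topC(r, 20)`.
#' @return character vector of the first C gene ids, ranking order.
#' @export
topC <- function(ranked, C) {
    stopifnot(is(ranked, "RankedFeatures"))
    f <- length(ranked@geneIds)
    if (C < 1 || C > f) stop("C must lie in [1, ", f, "]")
    ranked@geneIds[seq_len(C)]
}

#' Repeated-forest gene ranking on a training set
#'
#' Runs [rfImportance()] `config$nRepetitions` times with seeds
#' `baseSeed + 0, 1, ...` and averages the importances into a single
#' [RankedFeatures-class] via [averageRank()].
#'
#' @inheritParams rfImportance
#' @param baseSeed overrides `config$baseSeed` when given.
#' @return a [RankedFeatures-class].
#' @export
rankGenes <- function(exprTrain, labelsTrain, config = rfConfig(),
                      baseSeed = config$baseSeed) {
    imps <- lapply(seq_len(config$nRepetitions) - 1L, function(b)
        rfImportance(exprTrain, labelsTrain, config, repSeed = baseSeed + b))
    fp <- sprintf("n=%d;f=%d;sum=%.8g;seed=%d", ncol(exprTrain),
                  nrow(exprTrain), sum(exprTrain), baseSeed)
    averageRank(imps, source = fp)
}
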