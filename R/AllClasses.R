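#' @import methods
#' @importFrom stats approx coef lm lm.fit median p.adjust pnorm predict
#'   quantile rbinom rnbinom rnorm runif sd setNames var wilcox.test
#' @importFrom utils head write.table read.delim
NULL

#' Configuration for the synthetic multi-site cohort generator
#'
#' Holds every knob of the negative-binomial cohort simulator: cohort
#' composition, planted differential signal, site batch structure, technical
#' covariate effects and the mean-dispersion trend. Defaults emulate the
#' structure of a multi-centre early-disease whole-blood cohort: a roughly
#' 2:1 case:control imbalance spread over 25 clinical sites, several sites
#' with fewer than two controls, multiplicative per-site batch offsets, sex
#' and RNA-integrity (RIN) covariate effects, and a small planted set of
#' informative genes with modest fold-changes.
#'
#' @slot nCases,nControls number of case / control samples.
#' @slot nGenes total number of genes f.
#' @slot nSites number of clinical sites samples are spread over.
#' @slot nInformative number of genes with a planted non-zero log2
#'   fold-change between cases and controls.
#' @slot lfcRange length-2 numeric, range of planted |log2 fold-change|
#'   magnitudes (signs are random).
#' @slot batchSd standard deviation of the per-site log2 batch offsets.
#' @slot betaSex additive log2 expression shift for male samples.
#' @slot betaRin additive log2 expression shift per RIN unit.
#' @slot libsizeLogSd standard deviation of log library-size factors.
#' @slot dispersionParams named numeric (a0, a1) of the dispersion trend
#'   alpha(mu) = a1/mu + a0 (variance = mu + alpha*mu^2).
#' @slot baselineMeanLogRange length-2 numeric, range of per-gene baseline
#'   log2 mean expression.
#' @slot fracSmallSites fraction of sites forced to carry fewer than two
#'   control samples (exercises the small-site exclusion rule).
#' @slot ageLinkedSignal logical; couple the planted effect size to the age
#'   class of cases (late-onset cases express the signal more strongly).
#' @slot seed integer seed making the cohort reproducible.
#'
#' @seealso [simConfig()] for the user-facing constructor,
#'   [simulateCohort()] to draw a cohort.
#' @export
setClass("SimConfig", representation(
    nCases = "numeric", nControls = "numeric", nGenes = "numeric",
    nSites = "numeric", nInformative = "numeric", lfcRange = "numeric",
    batchSd = "numeric", betaSex = "numeric", betaRin = "numeric",
    libsizeLogSd = "numeric", dispersionParams = "numeric",
    baselineMeanLogRange = "numeric", fracSmallSites = "numeric",
    ageLinkedSignal = "logical", seed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(nCases = object@nCases, nControls = object@nControls,
             nGenes = object@nGenes, nSites = object@nSites)
    if (any(cnt < 1) || any(cnt != round(cnt)))
        msg <- c(msg, "nCases, nControls, nGenes, nSites must be positive integers")
    if (object@nSites < 2)
        msg <- c(msg, "at least 2 sites are required")
    if (object@nInformative < 0 || object@nInformative > object@nGenes)
        msg <- c(msg, "nInformative must lie in [0, nGenes]")
    if (object@nSites > object@nCases + object@nControls)
        msg <- c(msg, "more sites than samples")
    if (length(object@lfcRange) != 2L || diff(object@lfcRange) < 0 ||
        any(object@lfcRange < 0))
        msg <- c(msg, "lfcRange must be non-negative (min, max)")
    dp <- object@dispersionParams
    if (length(dp) != 2L || any(dp < 0))
        msg <- c(msg, "dispersionParams must be non-negative (a0, a1)")
    if (object@batchSd < 0 || object@libsizeLogSd < 0)
        msg <- c(msg, "batchSd and libsizeLogSd must be non-negative")
    if (object@fracSmallSites < 0 || object@fracSmallSites >= 1)
        msg <- c(msg, "fracSmallSites must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Ranked gene list with averaged random-forest importances
#'
#' Result container for the importance-ranking stage: gene identifiers
#' ordered by non-increasing mean importance over the forest repetitions,
#' ties broken lexicographically by gene id.
#'
#' @slot geneIds character, gene ids in ranking order (length f).
#' @slot meanImportance numeric, averaged importance aligned with `geneIds`.
#' @slot nRepetitions number of forest repetitions averaged over.
#' @slot source free-text fingerprint of the training data the ranking was
#'   computed from (used by the leakage audit).
#'
#' @seealso [averageRank()], [topC()]
#' @export
setClass("RankedFeatures", representation(
    geneIds = "character", meanImportance = "numeric",
    nRepetitions = "numeric", source = "character"))

setValidity("RankedFeatures", function(object) {
    msg <- character()
    if (length(object@geneIds) != length(object@meanImportance))
        msg <- c(msg, "geneIds and meanImportance lengths differ")
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "duplicate gene ids")
    if (is.unsorted(rev(object@meanImportance)))
        msg <- c(msg, "meanImportance must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' AUC-versus-C curve from repeated cross-validation
#'
#' Per-repetition validation AUC as a function of the number of top-ranked
#' features C, with pointwise median and mean absolute deviation (about the
#' median) across repetitions, and the argmax `cStar` of the median curve
#' (smallest C on ties).
#'
#' @slot grid integer vector of evaluated C values (strictly increasing).
#' @slot aucByRep numeric matrix, repetitions x grid, of pooled validation
#'   AUCs.
#' @slot medianAuc,madAuc numeric vectors on `grid`.
#' @slot cStar the C maximising the median AUC (smallest on ties).
#'
#' @seealso [aggregateCurve()], [interpolateCurve()]
#' @export
setClass("AucCurve", representation(
    grid = "numeric", aucByRep = "matrix",
    medianAuc = "numeric", madAuc = "numeric", cStar = "numeric"))

setValidity("AucCurve", function(object) {
    msg <- character()
    if (is.unsorted(object@grid, strictly = TRUE))
        msg <- c(msg, "grid must be strictly increasing")
    if (ncol(object@aucByRep) != length(object@grid))
        msg <- c(msg, "aucByRep columns must match grid")
    if (length(object@medianAuc) != length(object@grid) ||
        length(object@madAuc) != length(object@grid))
        msg <- c(msg, "median/MAD must be defined on the grid")
    if (length(object@cStar) != 1L ||
        object@cStar < min(object@grid) || object@cStar > max(object@grid))
        msg <- c(msg, "cStar must lie within the grid span")
    if (length(msg)) msg else TRUE
})

#' Result of a repeated nested cross-validation run
#'
#' Bundles the per-sample prediction records, the per-fold feature rankings
#' and the aggregated AUC curve of one [runNestedCv()] call.
#'
#' @slot predictions data.frame with columns sample_id, repetition, fold, C,
#'   predicted_probability, true_label. Each sample is predicted exactly once
#'   per (repetition, C).
#' @slot rankings list of [RankedFeatures-class] objects, one per
#'   (repetition, fold).
#' @slot curve an [AucCurve-class].
#' @slot topSets list of character vectors: the top-`cStar` gene set of each
#'   repetition's first-fold ranking consumer; see [selectionFrequency()].
#' @slot config list echoing the run configuration and seeds.
#' @export
setClass("NestedCvResult", representation(
    predictions = "data.frame", rankings = "list", curve = "AucCurve",
    topSets = "list", config = "list"))

#' @describeIn SimConfig-class compact display
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d cases / %d controls, %d genes (%d informative), %d sites\n",
        object@nCases, object@nControls, object@nGenes,
        object@nInformative, object@nSites))
    cat(sprintf("  |lfc| in [%.2f, %.2f], batch sd %.2f, dispersion a0=%.3g a1=%.3g, seed %d\n",
        object@lfcRange[1], object@lfcRange[2], object@batchSd,
        object@dispersionParams[1], object@dispersionParams[2], object@seed))
})

#' @describeIn RankedFeatures-class compact display
#' @param object a `RankedFeatures`
#' @export
setMethod("show", "RankedFeatures", function(object) {
    cat(sprintf("RankedFeatures: %d genes, mean over %d forest repetition(s)\n",
        length(object@geneIds), object@nRepetitions))
    n <- min(5L, length(object@geneIds))
    cat("  top:", paste(sprintf("%s (%.3g)", object@geneIds[seq_len(n)],
        object@meanImportance[seq_len(n)]), collapse = ", "), "\n")
})

#' @describeIn AucCurve-class compact display
#' @param object an `AucCurve`
#' @export
setMethod("show", "AucCurve", function(object) {
    i <- match(object@cStar, object@grid)
    cat(sprintf("AucCurve over C in {%s}, %d repetition(s)\n",
        paste(object@grid, collapse = ", "), nrow(object@aucByRep)))
    cat(sprintf("  max median AUC %.3f (MAD %.3f) at C* = %d\n",
        object@medianAuc[i], object@madAuc[i], as.integer(object@cStar)))
})

#' @describeIn NestedCvResult-class compact display
#' @param object a `NestedCvResult`
#' @export
setMethod("show", "NestedCvResult", function(object) {
    cat(sprintf("NestedCvResult: %d prediction records, %d fold rankings\n",
        nrow(object@predictions), length(object@rankings)))
    show(object@curve)
})

# ---- accessors -------------------------------------------------------------

#' @rdname RankedFeatures-class
#' @param x a `RankedFeatures`
#' @export
rankedGenes <- function(x) x@geneIds

#' @rdname RankedFeatures-class
#' @export
meanImportance <- function(x) setNames(x@meanImportance, x@geneIds)

#' @rdname AucCurve-class
#' @param x an `AucCurve`
#' @export
cStar <- function(x) x@cStar

#' @rdname AucCurve-class
#' @export
medianAuc <- function(x) setNames(x@medianAuc, x@grid)

#' @rdname AucCurve-class
#' @export
madAuc <- function(x) setNames(x@madAuc, x@grid)

#' @rdname NestedCvResult-class
#' @param x a `NestedCvResult`
#' @export
cvPredictions <- function(x) x@predictions

#' @rdname NestedCvResult-class
#' @export
cvCurve <- function(x) x@curve

#' @rdname NestedCvResult-class
#' @export
cvRankings <- function(x) x@rankings
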