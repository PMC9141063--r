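test_that("stratified folds balance classes and partition the cohort", {
    labels <- rep(c("case", "control"), c(390, 158))
    fold <- makeFolds(labels, k = 10, seed = 3)
    expect_length(fold, 548)
    expect_setequal(unique(fold), 1:10)
    perFold <- table(fold, labels)
    expect_true(all(perFold[, "case"] == 39))
    expect_true(all(perFold[, "control"] %in% 15:16))
    expect_identical(makeFolds(labels, 10, seed = 3), fold)
    expect_false(identical(makeFolds(labels, 10, seed = 4), fold))
    expect_error(makeFolds(rep(c("case", "control"), c(50, 5)), k = 10),
                 "fewer than k")
})

test_that("fold evaluation refuses overlapping train/validation sets", {
    d <- local({
        withr::local_seed(30)
        expr <- matrix(rnorm(20 * 40), 20, 40,
                       dimnames = list(paste0("g", 1:20), paste0("S", 1:40)))
        list(expr = expr, labels = rep(c("case", "control"), 20))
    })
    expect_error(runFold(d$expr, d$labels, 1:30, 25:40, cGrid = c(5, 10)),
                 "leakage")
    expect_error(runFold(d$expr, d$labels, 1:30, 31:40, cGrid = c(10, 5)),
                 "cGrid")
    expect_error(runFold(d$expr, d$labels, 1:30, 31:40, cGrid = c(5, 25)),
                 "cGrid")
})

test_that("fold rankings depend only on the training portion", {
    withr::local_seed(31)
    expr <- matrix(rnorm(30 * 60), 30, 60,
                   dimnames = list(paste0("g", 1:30), paste0("S", 1:60)))
    labels <- rep(c("case", "control"), 30)
    tr <- 1:40; va <- 41:60
    cfg <- rfConfig(nTrees = 50, nRepetitions = 2)
    r1 <- runFold(expr, labels, tr, va, cGrid = 5, rfCfg = cfg,
                  rankSeed = 8)
    # scramble validation labels and expression: ranking must not move
    labels2 <- labels; labels2[va] <- sample(labels[va])
    expr2 <- expr; expr2[, va] <- expr[, sample(va)]
    r2 <- runFold(expr2, labels2, tr, va, cGrid = 5, rfCfg = cfg,
                  rankSeed = 8)
    expect_identical(rankedGenes(r1$ranking), rankedGenes(r2$ranking))
    expect_identical(meanImportance(r1$ranking), meanImportance(r2$ranking))
})

test_that("null cohorts classify at chance over the whole C sweep", {
    se <- simulateCohort(simConfig(
        nCases = 80, nControls = 40, nGenes = 300, nSites = 3,
        nInformative = 0, fracSmallSites = 0, seed = 33))
    pp <- suppressWarnings(suppressMessages(preprocessCounts(se)))
    expr <- correctedExpr(pp)
    labels <- SummarizedExperiment::colData(pp)$label
    cv <- runNestedCv(expr, labels, cGrid = c(10, 50, 150),
                      rfCfg = rfConfig(nTrees = 100, nRepetitions = 2),
                      k = 4, nRep = 2, seed = 44)
    expect_true(all(cvCurve(cv)@aucByRep > 0.3 &
                    cvCurve(cv)@aucByRep < 0.7))
    expect_true(all(cvCurve(cv)@medianAuc > 0.4 - 0.05 &
                    cvCurve(cv)@medianAuc < 0.6 + 0.05))
})

test_that("strong planted signal yields high validation AUC at C >= signal size", {
    se <- strongCohort()
    pp <- strongPreprocessed()
    expr <- correctedExpr(pp)
    labels <- SummarizedExperiment::colData(pp)$label
    cv <- runNestedCv(expr, labels, cGrid = c(20, 60),
                      rfCfg = rfConfig(nTrees = 150, nRepetitions = 3),
                      k = 5, nRep = 2, seed = 55)
    expect_true(all(cvCurve(cv)@medianAuc > 0.9))
    # every sample validated exactly once per (repetition, C)
    rec <- cvPredictions(cv)
    counts <- table(rec$sample_id, rec$repetition, rec$C)
    expect_true(all(counts == 1))
    # deterministic rerun
    cv2 <- runNestedCv(expr, labels, cGrid = c(20, 60),
                       rfCfg = rfConfig(nTrees = 150, nRepetitions = 3),
                       k = 5, nRep = 2, seed = 55)
    expect_identical(cvPredictions(cv), cvPredictions(cv2))
})

test_that("curve aggregation matches brute-force median/MAD and tie rules", {
    withr::local_seed(36)
    grid <- c(5, 10, 20)
    rec <- expand.grid(sample_id = sprintf("S%02d", 1:20),
                       repetition = 1:4, C = grid)
    rec$true_label <- rep(rep(c("case", "control"), 10), 12)
    rec$predicted_probability <- runif(nrow(rec))
    curve <- aggregateCurve(rec, grid)
    for (j in seq_along(grid)) {
        aucs <- vapply(1:4, function(r) {
            sub <- rec[rec$repetition == r & rec$C == grid[j], ]
            aucBrute(sub$true_label, sub$predicted_probability)
        }, numeric(1))
        expect_equal(curve@aucByRep[j * 0 + seq_len(4), j], aucs,
                     ignore_attr = TRUE)
        expect_equal(curve@medianAuc[j], median(aucs))
        expect_equal(curve@madAuc[j], mean(abs(aucs - median(aucs))))
    }
    # single repetition: median is the curve, MAD zero
    one <- aggregateCurve(rec[rec$repetition == 1, ], grid)
    expect_equal(nrow(one@aucByRep), 1L)
    expect_true(all(one@madAuc == 0))
    # constant curve: C* is the smallest grid point
    flat <- rec; flat$predicted_probability <-
        as.numeric(flat$true_label == "case")
    expect_equal(cStar(aggregateCurve(flat, grid)), 5)
    # missing cell is an error
    expect_error(aggregateCurve(rec[!(rec$repetition == 2 & rec$C == 10), ],
                                grid), "missing cell")
})

test_that("curve interpolation is linear between grid points", {
    curve <- new("AucCurve", grid = c(10, 20, 40),
                 aucByRep = matrix(c(0.6, 0.7, 0.8), 1),
                 medianAuc = c(0.6, 0.7, 0.8), madAuc = c(0, 0.01, 0.02),
                 cStar = 40)
    out <- interpolateCurve(curve, c(10, 15, 30, 40))
    expect_equal(out$median_auc, c(0.6, 0.65, 0.75, 0.8))
    expect_error(interpolateCurve(curve, 5), "grid span")
})

test_that("DE-baseline classifier behaves at the oracle and null extremes", {
    se <- strongCohort()
    pp <- strongPreprocessed()
    truth <- cohortTruth(se)
    expr <- correctedExpr(pp)
    md <- as.data.frame(SummarizedExperiment::colData(pp))
    counts <- SummarizedExperiment::assay(pp, "counts")
    planted <- intersect(truth$informativeGeneIds, rownames(expr))
    oracle <- deBaseline(counts, expr, md, deGenes = planted, splitSeed = 2)
    expect_gt(oracle$auc, 0.9)
    withr::local_seed(37)
    nullGenes <- sample(setdiff(rownames(expr), truth$informativeGeneIds), 30)
    nulls <- vapply(1:10, function(s)
        deBaseline(counts, expr, md, deGenes = nullGenes,
                   splitSeed = s)$auc, numeric(1))
    # chance-level up to the small downward overfitting bias of held-out
    # AUC on a 15-sample test split; no positive signal
    expect_gt(mean(nulls), 0.30)
    expect_lt(mean(nulls), 0.62)
    expect_error(deBaseline(counts, expr, md, deGenes = character()),
                 "empty DE")
})
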