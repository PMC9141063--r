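toyCounts <- function(nGenes, nSamples, seed = 1) {
    withr::local_seed(seed)
    m <- matrix(rnbinom(nGenes * nSamples, mu = 50, size = 5),
                nGenes, nSamples,
                dimnames = list(sprintf("G%04d", seq_len(nGenes)),
                                sprintf("S%03d", seq_len(nSamples))))
    storage.mode(m) <- "integer"
    m
}

test_that("biotype filter keeps exactly the allowed biotypes, order preserved", {
    m <- toyCounts(5, 3)
    an <- data.frame(gene_id = rownames(m),
                     biotype = c("protein_coding", "protein_coding",
                                 "lincRNA", "rRNA", "pseudogene"))
    kept <- suppressMessages(filterBiotypes(m, c("protein_coding", "lincRNA"),
                                            annotation = an))
    expect_identical(rownames(kept), rownames(m)[1:3])
    all5 <- suppressMessages(filterBiotypes(m, unique(an$biotype),
                                            annotation = an))
    expect_identical(all5, m)
    expect_error(
        suppressMessages(filterBiotypes(m, "lincRNA",
                                        annotation = an[-2, ])),
        "G0002")
})

test_that("biotype filter retains the protein_coding + lincRNA universe at scale", {
    nPc <- 18727; nLinc <- 7444; nOther <- 500
    ids <- sprintf("G%05d", seq_len(nPc + nLinc + nOther))
    bt <- c(rep("protein_coding", nPc), rep("lincRNA", nLinc),
            rep("rRNA", nOther))
    withr::local_seed(4)
    ord <- sample(length(ids))
    m <- matrix(1L, length(ids), 2, dimnames = list(ids, c("a", "b")))
    an <- data.frame(gene_id = ids[ord], biotype = bt[ord])
    kept <- suppressMessages(filterBiotypes(m, c("protein_coding", "lincRNA"),
                                            annotation = an))
    expect_identical(nrow(kept), 26171L)
})

test_that("blacklist removal is a set difference with warnings for absences", {
    m <- toyCounts(200, 4)
    expect_identical(suppressMessages(dropBlacklist(m, character())), m)
    withr::local_seed(2)
    present <- sample(rownames(m), 60)
    bl <- c(present, sprintf("X%03d", 1:40))
    kept <- suppressWarnings(suppressMessages(dropBlacklist(m, bl)))
    expect_identical(nrow(kept), 140L)
    expect_identical(rownames(kept), setdiff(rownames(m), present))
    expect_warning(suppressMessages(dropBlacklist(m, bl)), "40")
    empty <- suppressWarnings(suppressMessages(dropBlacklist(m, rownames(m))))
    expect_identical(nrow(empty), 0L)
})

test_that("low-expression filter applies a strict count threshold", {
    m <- matrix(0L, 3, 10,
                dimnames = list(c("two", "allfive", "six"), NULL))
    m["two", 1:2] <- 6L          # 2 samples with > 5 counts, need >= 1
    m["allfive", ] <- 5L         # never strictly > 5: dropped
    m["six", ] <- 6L
    kept <- suppressMessages(filterLowExpression(m))
    expect_identical(rownames(kept), c("two", "six"))
    # brute-force equivalence on a simulated matrix
    big <- toyCounts(2000, 37, seed = 9)
    big[sample(length(big), length(big) / 2)] <- 0L
    kept2 <- suppressMessages(filterLowExpression(big))
    brute <- rownames(big)[vapply(seq_len(nrow(big)), function(g)
        sum(big[g, ] > 5) >= ceiling(0.10 * 37), logical(1))]
    expect_identical(rownames(kept2), brute)
})

test_that("median-of-ratios size factors match hand-computed toys", {
    m <- rbind(G1 = c(10, 20), G2 = c(100, 200), G3 = c(4, 8))
    colnames(m) <- c("a", "b")
    sf <- estimateSizeFactorsMoR(m)
    expect_equal(unname(sf["b"] / sf["a"]), 2)
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))      # geometric mean 1
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-6)
    # identical columns -> unit factors
    same <- cbind(a = c(3, 9, 27), b = c(3, 9, 27))
    expect_equal(unname(estimateSizeFactorsMoR(same)), c(1, 1))
    # scale equivariance
    m2 <- toyCounts(300, 5, seed = 3) + 1L
    sc <- m2; sc[, 2] <- sc[, 2] * 3L
    r1 <- estimateSizeFactorsMoR(m2)
    r2 <- estimateSizeFactorsMoR(sc)
    expect_equal(unname(r2[2] / r1[2] / (r2[1] / r1[1])), 3, tolerance = 1e-9)
    expect_error(estimateSizeFactorsMoR(matrix(c(0L, 1L, 2L, 0L), 2)),
                 "all counts > 0")
})

test_that("size factors agree with the reference median-of-ratios implementation", {
    skip_if_not_installed("DESeq2")
    m <- toyCounts(500, 8, seed = 21)
    expect_equal(unname(estimateSizeFactorsMoR(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m) /
                        exp(mean(log(DESeq2::estimateSizeFactorsForMatrix(m))))),
                 tolerance = 1e-8)
})

test_that("independent filtering cuts at the requested quantile, label-free", {
    m <- toyCounts(100, 6, seed = 5)
    sf <- estimateSizeFactorsMoR(m)
    expect_identical(suppressMessages(independentFilter(m, sf, 0)), m)
    half <- suppressMessages(independentFilter(m, sf, 0.5))
    expect_identical(nrow(half), 50L)
    stat <- rowMeans(sweep(m, 2, sf, `/`))
    expect_identical(rownames(half),
                     rownames(m)[stat >= quantile(stat, 0.5)])
    expect_error(suppressMessages(independentFilter(m, sf, 1)), "meanQuantile")
    # monotone: higher quantile never retains more genes
    q <- seq(0, 0.9, by = 0.1)
    kept <- vapply(q, function(x)
        nrow(suppressMessages(independentFilter(m, sf, x))), numeric(1))
    expect_true(all(diff(kept) <= 0))
})

test_that("the closed-form VST is monotone and asymptotically log2", {
    v <- function(n) nestedSelect:::vstClosedForm(n, a0 = 0.05, a1 = 1)
    expect_true(v(0) < v(1) && v(1) < v(100))
    expect_lt(abs((v(1e6) - log2(1e6)) - (v(1e5) - log2(1e5))), 0.01)
    xs <- sort(runif(100, 0, 1e4))
    expect_true(all(diff(v(xs)) > 0))
})

test_that("VST flattens the variance-mean relationship on NB data", {
    cfg <- simConfig(nCases = 150, nControls = 150, nGenes = 1500,
                     nSites = 2, nInformative = 0, batchSd = 0, betaSex = 0,
                     betaRin = 0, fracSmallSites = 0, seed = 31)
    counts <- SummarizedExperiment::assay(simulateCohort(cfg), "counts")
    counts <- suppressMessages(filterLowExpression(counts))
    sf <- estimateSizeFactorsMoR(counts)
    v <- suppressWarnings(vstTransform(counts, sf))
    norm <- sweep(counts, 2, sf, `/`)
    binRatio <- function(x) {
        m <- rowMeans(norm)
        bins <- cut(rank(m), 5)
        bv <- tapply(apply(x, 1, var), bins, median)
        max(bv) / min(bv)
    }
    expect_lt(binRatio(v), 3)
    expect_gt(binRatio(log2(norm + 1)), binRatio(v))
})

test_that("small-site exclusion reproduces the printed cohort arithmetic", {
    # 25 sites, 579 samples; four sites carrying 1 + 16 + 4 + 10 = 31
    # samples have at most one control each -> 548 remain
    withr::local_seed(8)
    smallSizes <- c("s14" = 1, "s26" = 16, "s55" = 4, "s59" = 10)
    nBig <- 579 - sum(smallSizes)
    bigSite <- sample(sprintf("b%02d", 1:21), nBig, replace = TRUE)
    md <- data.frame(
        site = c(bigSite, rep(names(smallSizes), smallSizes)),
        label = "case", stringsAsFactors = FALSE)
    # two controls per big site, at most one on the small ones
    for (s in unique(bigSite))
        md$label[which(md$site == s)[1:2]] <- "control"
    md$label[which(md$site == "s14")[1]] <- "control"
    md$label[which(md$site == "s26")[1]] <- "control"
    m <- matrix(1L, 5, nrow(md),
                dimnames = list(paste0("g", 1:5), paste0("S", seq_len(nrow(md)))))
    out <- suppressMessages(excludeSmallSites(m, metadata = md))
    expect_identical(ncol(out$counts), 548L)
    expect_false(any(out$metadata$site %in% names(smallSizes)))
    # identity when every site is fine
    ok <- md[md$site %in% unique(bigSite), ]
    out2 <- suppressMessages(excludeSmallSites(
        m[, seq_len(nrow(ok))], metadata = ok))
    expect_identical(ncol(out2$counts), nrow(ok))
})

test_that("small-site exclusion equals a brute-force per-site scan", {
    withr::local_seed(12)
    md <- data.frame(site = sample(paste0("s", 1:8), 200, replace = TRUE),
                     label = sample(c("case", "control"), 200, TRUE,
                                    prob = c(0.8, 0.2)))
    m <- matrix(1L, 3, 200, dimnames = list(paste0("g", 1:3),
                                            paste0("S", 1:200)))
    out <- suppressMessages(excludeSmallSites(m, metadata = md))
    ctrlPerSite <- tapply(md$label == "control", md$site, sum)
    keepSites <- names(ctrlPerSite)[ctrlPerSite >= 2]
    expect_identical(ncol(out$counts), sum(md$site %in% keepSites))
})

test_that("control-anchored batch removal recovers planted offsets exactly", {
    withr::local_seed(14)
    g <- 40; n <- 60
    site <- factor(rep(c("A", "B", "C"), each = 20))
    label <- rep(rep(c("control", "case"), c(5, 15)), 3)
    md <- data.frame(site = site, label = label)
    # noiseless base: constant per gene, so offsets are exactly identifiable
    base <- matrix(rep(rnorm(g, 6), n), g, n,
                   dimnames = list(paste0("g", 1:g), paste0("S", 1:n)))
    off <- c(A = 1.5, B = -0.5, C = -1)        # sums to zero
    noisy <- base + matrix(off[site], g, n, byrow = TRUE)
    fixed <- removeSiteBatch(noisy, md)
    expect_equal(fixed, base, ignore_attr = TRUE, tolerance = 1e-8)
    est <- attr(fixed, "siteOffsets")
    expect_equal(est["A", ], rep(1.5, g), ignore_attr = TRUE,
                 tolerance = 1e-8)
    # batch-free input passes through unchanged
    expect_equal(removeSiteBatch(base, md), base, ignore_attr = TRUE,
                 tolerance = 1e-8)
    # zero-control site is refused
    md2 <- md; md2$label[md2$site == "A"] <- "case"
    expect_error(removeSiteBatch(noisy, md2), "excludeSmallSites")
})

test_that("batch removal shrinks between-site control variance under NB noise", {
    se <- strongCohort()
    pp <- suppressWarnings(suppressMessages(vstTransform(
        suppressMessages(filterLowExpression(se)))))
    md <- as.data.frame(SummarizedExperiment::colData(se))
    v <- SummarizedExperiment::assay(pp, "vst")
    fixed <- removeSiteBatch(v, md)
    betweenSiteVar <- function(x) {
        ctrl <- md$label == "control"
        apply(x[, ctrl], 1, function(row)
            var(tapply(row, droplevels(md$site[ctrl]), mean)))
    }
    expect_gt(mean(betweenSiteVar(fixed) <= betweenSiteVar(v) + 1e-12), 0.95)
})

test_that("covariate residualization removes planted linear effects", {
    withr::local_seed(15)
    g <- 30; n <- 80
    md <- data.frame(sex = sample(c("M", "F"), n, TRUE), rin = rnorm(n, 8, 1.5))
    flat <- matrix(rep(rnorm(g, 5), n), g, n,
                   dimnames = list(paste0("g", 1:g), paste0("S", 1:n)))
    planted <- flat +
        matrix(0.8 * (md$sex == "M"), g, n, byrow = TRUE) +
        matrix(0.3 * md$rin, g, n, byrow = TRUE)
    # noiseless planted effect: removed exactly, intercept retained
    expect_equal(removeCovariates(planted, metadata = md), flat,
                 tolerance = 1e-8, ignore_attr = TRUE)
    # covariate-free noise passes through up to its own small projection
    # onto the covariates (compare after per-gene centring: the intercept
    # trade-off with the non-centred RIN column shifts gene means)
    base <- flat + matrix(rnorm(g * n), g, n)
    out <- removeCovariates(base, metadata = md)
    d <- out - base
    expect_lt(mean(abs(d - rowMeans(d))), 0.25)
    expect_gt(cor(as.vector(out - rowMeans(out)),
                  as.vector(base - rowMeans(base))), 0.97)
    # residual RIN correlation drops
    shifted <- base + matrix(0.3 * md$rin, g, n, byrow = TRUE)
    corWith <- function(x) mean(abs(apply(x, 1, cor, md$rin)))
    expect_lt(corWith(removeCovariates(shifted, metadata = md)),
              corWith(shifted))
    # constant covariate is skipped with a warning
    md$sex <- "M"
    expect_warning(removeCovariates(shifted, metadata = md), "constant")
})

test_that("cascade stages before batch correction ignore the labels", {
    se <- strongCohort()
    sePerm <- se
    withr::local_seed(16)
    sePerm$label <- sample(se$label)
    run <- function(x) {
        x <- filterBiotypes(x)
        x <- filterLowExpression(x)
        sf <- estimateSizeFactorsMoR(x)
        rownames(independentFilter(x, sf, 0.4))
    }
    expect_identical(suppressMessages(run(se)), suppressMessages(run(sePerm)))
})

test_that("full cascade emits a coherent report and finite expression", {
    pp <- strongPreprocessed()
    rep <- S4Vectors::metadata(pp)$preprocessReport
    expect_true(rep$afterBiotype <= rep$input[1])
    expect_true(rep$afterLowExpression <= rep$afterBiotype)
    expect_true(rep$afterIndependentFilter <= rep$afterLowExpression)
    expect_identical(nrow(pp), as.integer(rep$afterIndependentFilter))
    expr <- correctedExpr(pp)
    expect_true(all(is.finite(expr)))
    # independent filter default removes about 40% of genes
    expect_equal(rep$afterIndependentFilter / rep$afterLowExpression, 0.6,
                 tolerance = 0.02)
})
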