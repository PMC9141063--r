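#' Create a synthetic-cohort configuration
#'
#' Constructor for [SimConfig-class]. Defaults emulate a multi-centre
#' early-disease whole-blood RNA-seq cohort: 390 cases and 189 controls
#' (about 2:1) spread over 25 sites of uneven size, a handful of sites with
#' fewer than two controls, per-site multiplicative batch effects, sex and
#' RIN technical covariates, log-normal library sizes, negative-binomial
#' counts following the dispersion trend alpha(mu) = a1/mu + a0, and a small
#' planted set of informative genes with modest |log2 fold-changes| in
#' \[0.2, 0.8\] so the case/control signal is deliberately weak.
#'
#' @param nCases,nControls cohort composition (default 390 / 189).
#' @param nGenes total genes simulated (default 2000; a desk-scale stand-in
#'   for a genome-wide panel).
#' @param nSites number of clinical sites (default 25).
#' @param nInformative genes with planted signal (default 50).
#' @param lfcRange range of planted |log2 fold-change| (default c(0.2, 0.8)).
#' @param batchSd sd of per-site log2 batch offsets (default 0.3).
#' @param betaSex log2 shift for male samples (default 0.1).
#' @param betaRin log2 shift per RIN unit about the cohort typical RIN of 8
#'   (default 0.05).
#' @param libsizeLogSd sd of log library-size factors (default 0.25).
#' @param dispersionParams c(a0, a1) of the trend alpha(mu) = a1/mu + a0.
#'   The default asymptotic dispersion a0 = 0.5 corresponds to an
#'   inter-individual log2 standard deviation of about 1 for well-expressed
#'   genes, the scale implied by reported per-gene fold-change standard
#'   errors (about 0.15 log2 units at roughly 550 samples) in multi-site
#'   whole-blood cohorts; it keeps the per-gene case/control signal weak, as
#'   such cohorts show.
#' @param baselineMeanLogRange range of per-gene baseline log2 mean counts
#'   (default c(1, 9)).
#' @param fracSmallSites fraction of sites forced to have fewer than two
#'   controls (default 4/25, i.e. four small sites out of 25).
#' @param ageLinkedSignal couple planted effect size to case age class
#'   (late-onset cases carry a stronger signal); default FALSE.
#' @param seed RNG seed (default 1).
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nCases = 40, nControls = 20, nGenes = 100, nSites = 4)
#' cfg
#' @export
simConfig <- function(nCases = 390, nControls = 189, nGenes = 2000,
                      nSites = 25, nInformative = 50,
                      lfcRange = c(0.2, 0.8), batchSd = 0.3,
                      betaSex = 0.1, betaRin = 0.05, libsizeLogSd = 0.25,
                      dispersionParams = c(a0 = 0.5, a1 = 2),
                      baselineMeanLogRange = c(1, 9),
                      fracSmallSites = 4 / 25, ageLinkedSignal = FALSE,
                      seed = 1) {
    new("SimConfig", nCases = nCases, nControls = nControls, nGenes = nGenes,
        nSites = nSites, nInformative = nInformative, lfcRange = lfcRange,
        batchSd = batchSd, betaSex = betaSex, betaRin = betaRin,
        libsizeLogSd = libsizeLogSd,
        dispersionParams = setNames(as.numeric(dispersionParams), c("a0", "a1")),
        baselineMeanLogRange = baselineMeanLogRange,
        fracSmallSites = fracSmallSites, ageLinkedSignal = ageLinkedSignal,
        seed = seed)
}

#' Assign samples to clinical sites
#'
#' Distributes samples over sites with uneven site sizes (Dirichlet-like
#' weights) and then rearranges control samples so that a chosen fraction of
#' sites ends up with fewer than two controls — the configuration the
#' small-site exclusion rule must handle — while every remaining site keeps
#' at least two controls.
#'
#' @param labels character vector of "case"/"control" per sample.
#' @param nSites number of sites (>= 2).
#' @param fracSmallSites fraction of sites forced to carry < 2 controls.
#' @param seed RNG seed.
#' @return factor of site labels ("s01", "s02", ...) aligned with `labels`.
#' @examples
#' table(assignSites(rep(c("case", "control"), c(40, 20)), nSites = 5,
#'                   fracSmallSites = 0.2, seed = 1))
#' @export
assignSites <- function(labels, nSites, fracSmallSites = 0, seed = 1) {
    labels <- checkBinaryLabels(labels)
    n <- length(labels)
    if (nSites < 2) stop("nSites must be >= 2")
    if (nSites > n) stop("more sites than samples")
    nSmall <- round(fracSmallSites * nSites)
    if (fracSmallSites > 0) nSmall <- max(1L, nSmall)
    if (nSites - nSmall < 1) stop("fracSmallSites leaves no regular site")
    nCtrl <- sum(labels == "control")
    if (nCtrl < 2 * (nSites - nSmall))
        stop("not enough controls for ", nSites - nSmall,
             " sites with >= 2 controls each")
    withSeed(seed, {
        w <- rgammaWeights(nSites)
        site <- sample.int(nSites, n, replace = TRUE, prob = w)
        # guarantee non-empty sites
        for (s in setdiff(seq_len(nSites), unique(site))) {
            big <- which(site == names(which.max(table(site)))[1])
            site[sample(big, 1L)] <- s
        }
        small <- sample.int(nSites, nSmall)
        ctrlIdx <- which(labels == "control")
        # small sites keep at most one control; displaced controls go to the
        # regular site currently poorest in controls
        regular <- setdiff(seq_len(nSites), small)
        for (s in small) {
            here <- intersect(ctrlIdx, which(site == s))
            keep <- if (length(here) && s %% 2L == 1L) here[1L] else integer()
            for (i in setdiff(here, keep)) {
                tab <- vapply(regular, function(r)
                    sum(labels[site == r] == "control"), numeric(1))
                site[i] <- regular[which.min(tab)]
            }
        }
        # top up regular sites to >= 2 controls from the richest site
        repeat {
            tab <- vapply(regular, function(r)
                sum(labels[site == r] == "control"), numeric(1))
            needy <- regular[tab < 2]
            if (!length(needy)) break
            donor <- regular[which.max(tab)]
            i <- intersect(ctrlIdx, which(site == donor))[1L]
            site[i] <- needy[1L]
        }
    })
    factor(sprintf("s%02d", site), levels = sprintf("s%02d", seq_len(nSites)))
}

rgammaWeights <- function(k) {
    w <- stats::rgamma(k, shape = 2, rate = 1)
    w / sum(w)
}

truncNorm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi))
        x[bad] <- rnorm(sum(bad), mean, sd)
    x
}

#' Simulate a multi-site case/control RNA-seq cohort with known truth
#'
#' Draws gene-level counts from a negative-binomial model
#' \deqn{\log_2 \mu_{gi} = b_g + \log_2 s_i + \gamma_{site(i)} +
#'   \beta_{sex}\,male_i + \beta_{rin}(rin_i - 8) + \lambda_g\,case_i}
#' with per-gene dispersion \eqn{\alpha_g = a_1/2^{b_g} + a_0} (variance
#' \eqn{\mu + \alpha\mu^2}), so every downstream stage — filtering,
#' normalization, batch removal, differential expression, ranking and
#' cross-validation — can be tested against planted ground truth.
#'
#' Sample metadata carries disease label, site, sex, RIN (Normal(8, 1.7)
#' truncated to \[1, 10\]), age and endophenotype fields (cognitive class,
#' REM-sleep behaviour disorder, motor subtype, olfactory class) drawn from
#' class-specific marginal frequencies independent of expression, unless
#' `ageLinkedSignal` couples case age class to the planted effect size.
#' Gene annotation assigns biotypes (62% protein_coding, 25% lincRNA, the
#' rest split over rRNA/pseudogene/snoRNA) so the biotype filter is
#' exercised; informative genes are drawn from the protein_coding/lincRNA
#' pool with baseline log2 mean >= 4 so the planted signal survives the
#' label-independent filters.
#'
#' @param config a [SimConfig-class], e.g. from [simConfig()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with integer assay
#'   `counts`, `rowData` columns gene_id/symbol/biotype, `colData` columns
#'   sample_id/label/site/sex/rin/age/age_class/moca_class/rbd/motor_class/
#'   smell_class, and `metadata(se)$truth` holding informativeGeneIds,
#'   trueLfc, siteOffsets and trueSizeFactors.
#' @examples
#' se <- simulateCohort(simConfig(nCases = 30, nControls = 16, nGenes = 50,
#'                                nSites = 3, nInformative = 5, seed = 7))
#' dim(se)
#' table(se$label)
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    n <- config@nCases + config@nControls
    g <- config@nGenes
    withSeed(config@seed, {
        geneIds <- sprintf("G%05d", seq_len(g))
        biotype <- sample(c("protein_coding", "lincRNA", "rRNA",
                            "pseudogene", "snoRNA"),
                          g, replace = TRUE,
                          prob = c(0.62, 0.25, 0.04, 0.06, 0.03))
        baseline <- runif(g, config@baselineMeanLogRange[1],
                          config@baselineMeanLogRange[2])
        eligible <- which(biotype %in% c("protein_coding", "lincRNA") &
                          baseline >= 4)
        if (length(eligible) < config@nInformative)
            stop("too few well-expressed protein_coding/lincRNA genes ",
                 "to plant ", config@nInformative, " informative genes")
        informative <- sort(sample(eligible, config@nInformative))
        trueLfc <- numeric(g)
        if (config@nInformative > 0)
            trueLfc[informative] <-
                sample(c(-1, 1), config@nInformative, replace = TRUE) *
                runif(config@nInformative, config@lfcRange[1],
                      config@lfcRange[2])

        label <- rep(c("case", "control"), c(config@nCases, config@nControls))
        site <- assignSites(label, config@nSites, config@fracSmallSites,
                            seed = deriveSeed(config@seed, "sites"))
        siteOffsets <- setNames(rnorm(config@nSites, 0, config@batchSd),
                                levels(site))
        sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.645, 0.355))
        rin <- truncNorm(n, 8, 1.7, 1, 10)
        age <- ifelse(label == "case", rnorm(n, 62, 10), rnorm(n, 61, 11))
        sf <- exp(rnorm(n, 0, config@libsizeLogSd))
        sf <- sf / exp(mean(log(sf)))

        isCase <- as.numeric(label == "case")
        effect <- outer(trueLfc, isCase)           # genes x samples
        if (config@ageLinkedSignal) {
            mult <- ifelse(age >= 56, 1.25, 0.5)
            effect <- sweep(effect, 2, ifelse(isCase == 1, mult, 1), `*`)
        }
        log2mu <- outer(baseline, rep(1, n)) +
            matrix(log2(sf), g, n, byrow = TRUE) +
            matrix(siteOffsets[as.character(site)], g, n, byrow = TRUE) +
            matrix(config@betaSex * (sex == "M"), g, n, byrow = TRUE) +
            matrix(config@betaRin * (rin - 8), g, n, byrow = TRUE) +
            effect
        mu <- 2^log2mu
        a0 <- config@dispersionParams[["a0"]]
        a1 <- config@dispersionParams[["a1"]]
        alpha <- a1 / 2^baseline + a0
        size <- ifelse(alpha > 0, 1 / alpha, Inf)
        counts <- matrix(rnbinom(g * n, mu = mu,
                                 size = rep(size, n)), g, n)
        storage.mode(counts) <- "integer"

        # endophenotype marginals by class (independent of expression)
        marg <- function(pCase, pCtrl, yes, no)
            ifelse(runif(n) < ifelse(isCase == 1, pCase, pCtrl), yes, no)
        moca <- marg(0.33, 0.005, "MoCA<=26", "MoCA>26")
        rbd <- marg(0.37, 0.20, "RBD", "noRBD")
        motor <- marg(0.70, 0.13, "TD", "PIGD/indet")
        smell <- marg(0.12, 0.63, "normosmia", "hypo/anosmia")
    })
    sampleIds <- sprintf("S%04d", seq_len(n))
    dimnames(counts) <- list(geneIds, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_id = geneIds, symbol = geneIds,
                                       biotype = biotype, row.names = geneIds),
        colData = S4Vectors::DataFrame(
            sample_id = sampleIds, label = label, site = site, sex = sex,
            rin = rin, age = age,
            age_class = ifelse(age >= 56, "age>=56", "age<56"),
            moca_class = moca, rbd = rbd, motor_class = motor,
            smell_class = smell, row.names = sampleIds))
    S4Vectors::metadata(se)$truth <- list(
        informativeGeneIds = geneIds[informative],
        trueLfc = setNames(trueLfc, geneIds),
        siteOffsets = siteOffsets,
        trueSizeFactors = setNames(sf, sampleIds))
    S4Vectors::metadata(se)$simConfig <- config
    se
}

#' Ground truth of a simulated cohort
#'
#' @param se a `SummarizedExperiment` from [simulateCohort()].
#' @return list with informativeGeneIds, trueLfc, siteOffsets,
#'   trueSizeFactors.
#' @export
cohortTruth <- function(se) {
    tr <- S4Vectors::metadata(se)$truth
    if (is.null(tr)) stop("no truth metadata: not a simulated cohort?")
    tr
}
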