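# Shared fixtures, memoised so expensive cohorts are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
    if (!exists(key, envir = .fixtures))
        assign(key, builder(), envir = .fixtures)
    get(key, envir = .fixtures)
}

# small cohort with clean sites (no small-site exclusion) and strong signal
strongCohort <- function() memo("strong", function() {
    simulateCohort(simConfig(
        nCases = 100, nControls = 50, nGenes = 400, nSites = 4,
        nInformative = 20, lfcRange = c(1.5, 2), fracSmallSites = 0,
        seed = 11))
})

strongPreprocessed <- function() memo("strongPP", function()
    suppressMessages(preprocessCounts(strongCohort())))

# desk-scale default cohort: 300 samples 2:1, 2000 genes, 50 planted,
# weak signal — the study-condition configuration
defaultCohort <- function(seed = 101) {
    simulateCohort(simConfig(nCases = 200, nControls = 100, seed = seed))
}

# brute-force BH step-up, straight from the definition
bhBrute <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- pmin(1, m * p[ord] / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[ord] <- adj
    out
}

# exhaustive pair-counting AUC
aucBrute <- function(labels, scores) {
    cs <- scores[labels == "case"]; ct <- scores[labels == "control"]
    tot <- 0
    for (a in cs) for (b in ct)
        tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(cs) * length(ct))
}

# exact two-sided Wilcoxon rank-sum p by enumeration of rank assignments
# (distinct values assumed)
wilcoxExactBrute <- function(x, y) {
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n)])
    combs <- utils::combn(n + m, n)
    ws <- apply(combs, 2, function(i) sum(rank(seq_len(n + m))[i]))
    mu <- n * (n + m + 1) / 2
    mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}
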