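# Internal helpers shared across the pipeline stages.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Deterministic fan-out of one master seed into per-stage / per-repetition
# streams. Keyed on small integers and stage names so any pipeline subset is
# independently reproducible; result always lies in [1, 2^31 - 2].
deriveSeed <- function(master, ...) {
    keys <- list(...)
    h <- as.double(master) %% 2147483647
    for (k in keys) {
        if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
        h <- (h * 48271 + as.double(k) + 1) %% 2147483647
    }
    as.integer(h %% 2147483645) + 1L
}

# Stage logging: single place so the cascade's gene/sample accounting is
# uniform and can be silenced via suppressMessages().
stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

assayCounts <- function(x) {
    if (is(x, "SummarizedExperiment"))
        return(SummarizedExperiment::assay(x, 1L))
    if (!is.matrix(x))
        stop("expected a matrix or SummarizedExperiment")
    x
}

checkBinaryLabels <- function(labels) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("case", "control"))
    if (length(bad))
        stop("labels must be 'case'/'control'; found: ",
             paste(bad, collapse = ", "))
    labels
}
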