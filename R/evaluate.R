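#' Confusion counts and threshold metrics
#'
#' Thresholds predicted case probabilities at `threshold` (prediction =
#' case when probability >= threshold; the positive class is "case") and
#' computes accuracy, sensitivity, specificity, balanced accuracy and F1
#' from the confusion counts:
#' \deqn{Acc = \frac{TP+TN}{TP+TN+FP+FN},\quad Sens = \frac{TP}{TP+FN},\quad
#'   Spec = \frac{TN}{TN+FP}}
#' \deqn{BalAcc = \frac{Sens+Spec}{2},\quad F1 = \frac{2TP}{2TP+FP+FN}}
#' Metrics with a zero denominator are returned `NA` with a warning.
#'
#' @param labels "case"/"control" per sample.
#' @param probabilities predicted case probabilities in \[0, 1\].
#' @param threshold decision threshold (default 0.5).
#' @return list with `counts` (named TP/FP/TN/FN), `metrics` (named numeric)
#'   and `threshold`.
#' @examples
#' confusionMetrics(c("case", "case", "control"), c(0.9, 0.4, 0.2))$metrics
#' @export
confusionMetrics <- function(labels, probabilities, threshold = 0.5) {
    labels <- checkBinaryLabels(labels)
    if (!length(labels)) stop("empty input")
    stopifnot(length(labels) == length(probabilities),
              all(probabilities >= 0 & probabilities <= 1))
    pred <- probabilities >= threshold
    isCase <- labels == "case"
    counts <- c(TP = sum(pred & isCase), FP = sum(pred & !isCase),
                TN = sum(!pred & !isCase), FN = sum(!pred & isCase))
    safe <- function(num, den, what) {
        if (den == 0) { warning(what, ": zero denominator"); return(NA_real_) }
        num / den
    }
    sens <- safe(counts["TP"], counts["TP"] + counts["FN"], "sensitivity")
    spec <- safe(counts["TN"], counts["TN"] + counts["FP"], "specificity")
    metrics <- c(
        accuracy = unname((counts["TP"] + counts["TN"]) / sum(counts)),
        sensitivity = unname(sens),
        specificity = unname(spec),
        balanced_accuracy = unname((sens + spec) / 2),
        f1 = unname(safe(2 * counts["TP"],
                         2 * counts["TP"] + counts["FP"] + counts["FN"], "F1")))
    list(counts = counts, metrics = metrics, threshold = threshold)
}

#' Area under the ROC curve by pair counting
#'
#' \deqn{AUC = \frac{\#\{(i,j): s_i > s_j\} + 0.5\,\#\{s_i = s_j\}}
#'   {n_{case}\, n_{control}}}
#' over all case/control pairs (i a case, j a control), computed via
#' mid-ranks, which equals the trapezoidal area under the ROC curve.
#'
#' @param labels "case"/"control"; both classes must be present.
#' @param probabilities scores (higher = more case-like).
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c("case", "case", "control", "control"), c(0.9, 0.4, 0.5, 0.1))
#' @export
rocAuc <- function(labels, probabilities) {
    labels <- checkBinaryLabels(labels)
    n1 <- sum(labels == "case"); n0 <- sum(labels == "control")
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    r <- rank(probabilities)  # mid-ranks handle ties with 0.5 credit
    (sum(r[labels == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare predicted probabilities between endophenotype groups
#'
#' Among case samples only, averages each subject's predicted probability
#' over the cross-validation repetitions at one feature-set size C, splits
#' subjects by a binary endophenotype column and compares the two groups
#' with a two-sided Wilcoxon rank-sum test (exact for small samples without
#' ties, normal approximation with tie correction otherwise). Subjects with
#' a missing endophenotype value are dropped with a logged count.
#'
#' @param predictions data.frame of prediction records (columns sample_id,
#'   repetition, C, predicted_probability, true_label), e.g.
#'   `cvPredictions(runNestedCv(...))`.
#' @param metadata data.frame indexed by sample id carrying the grouping
#'   column.
#' @param grouping name of the binary metadata column (e.g. "rbd",
#'   "age_class").
#' @param C feature-set size at which probabilities are taken (default: the
#'   largest C present).
#' @return list with `grouping`, `groups`, `n`, `means` (mean predicted
#'   probability per group) and `p` (`NA` with a warning if a group has
#'   fewer than 2 subjects).
#' @export
endophenotypeTest <- function(predictions, metadata, grouping,
                              C = max(predictions$C)) {
    rec <- predictions[predictions$C == C &
                       predictions$true_label == "case", ]
    if (!nrow(rec)) stop("no case predictions at C = ", C)
    probs <- tapply(rec$predicted_probability, rec$sample_id, mean)
    grp <- metadata[names(probs), grouping]
    drop <- is.na(grp)
    if (any(drop))
        stageLog("endophenotypeTest", "%d subject(s) missing '%s' dropped",
                 sum(drop), grouping)
    probs <- probs[!drop]; grp <- factor(grp[!drop])
    if (nlevels(grp) != 2)
        stop("grouping '", grouping, "' must have exactly 2 levels among cases")
    ns <- table(grp)
    means <- tapply(probs, grp, mean)
    if (any(ns < 2)) {
        warning("group with < 2 subjects: test skipped")
        p <- NA_real_
    } else {
        p <- suppressWarnings(
            wilcox.test(probs[grp == levels(grp)[1]],
                        probs[grp == levels(grp)[2]],
                        alternative = "two.sided")$p.value)
    }
    list(grouping = grouping, groups = levels(grp),
         n = as.numeric(ns), means = as.numeric(means), p = p)
}
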