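## Evaluation: confusion counts, threshold metrics (ACC, Sn, Sp, MCC),
## rank-based ROC AUC, and the chain-level cross-validation protocol.

#' Confusion counts for binary labels
#'
#' @param truth,predicted Equal-length 0/1 vectors; positives (1) are
#'   interface residues.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusionCounts <- function(truth, predicted) {
    if (length(truth) != length(predicted))
        stop("input error: label vectors differ in length")
    if (!length(truth)) stop("input error: empty label vectors")
    if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
        stop("input error: labels must be 0/1")
    c(TP = sum(truth == 1 & predicted == 1),
      FP = sum(truth == 0 & predicted == 1),
      TN = sum(truth == 0 & predicted == 0),
      FN = sum(truth == 1 & predicted == 0))
}

#' Threshold-dependent classification metrics
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))` from a set of
#' confusion counts.  When a sensitivity or specificity denominator is
#' zero the metric is undefined and reported as `NA`; when any MCC
#' denominator factor is zero the MCC is 0 by the usual convention.
#'
#' @param counts Named vector with elements `TP`, `FP`, `TN`, `FN`
#'   (as from [confusionCounts()]).
#' @return Named numeric vector `ACC`, `Sn`, `Sp`, `MCC`.
#' @export
#' @examples
#' classificationMetrics(c(TP = 3, FP = 1, TN = 5, FN = 1))
classificationMetrics <- function(counts) {
    need <- c("TP", "FP", "TN", "FN")
    stopifnot(all(need %in% names(counts)))
    ## doubles: the MCC denominator overflows 32-bit integers easily
    tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
    tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
    if (any(c(tp, fp, tn, fn) < 0)) stop("input error: negative counts")
    total <- tp + fp + tn + fn
    if (total < 1) stop("input error: all counts are zero")
    acc <- (tp + tn) / total
    sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    den <- (tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)
    mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
    c(ACC = acc, Sn = sn, Sp = sp, MCC = mcc)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive is scored higher
#' than a randomly chosen negative, with ties counted half.  Computed
#' by the rank-sum (Mann-Whitney) formulation with midranks, which
#' equals the trapezoidal area under the ROC curve over all thresholds.
#'
#' @param truth 0/1 vector; both classes must be present.
#' @param scores Numeric scores (higher means more interface-like).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' rocAUC(c(1, 1, 0, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
rocAUC <- function(truth, scores) {
    if (length(truth) != length(scores))
        stop("input error: truth and scores differ in length")
    if (!all(truth %in% c(0, 1)))
        stop("input error: truth must be 0/1")
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    if (n1 == 0L || n0 == 0L)
        stop("undefined AUC: both classes must be present")
    r <- rank(scores, ties.method = "average")
    (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Cumulative true/false positive rates over all score thresholds, for
#' plotting or export.
#'
#' @inheritParams rocAUC
#' @return A `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
rocPoints <- function(truth, scores) {
    ord <- order(scores, decreasing = TRUE)
    truth <- truth[ord]; scores <- scores[ord]
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    keep <- !duplicated(scores, fromLast = TRUE)
    data.frame(threshold = c(Inf, scores[keep]),
               fpr = c(0, cumsum(truth == 0)[keep] / n0),
               tpr = c(0, cumsum(truth == 1)[keep] / n1))
}

#' Build an evaluation report
#'
#' @param truth 0/1 vector of reference labels.
#' @param scores Predicted interface probabilities.
#' @param threshold Classification threshold (default 0.5).
#' @return An [EvalReport-class].  AUC is `NA` when the truth is
#'   single-class.
#' @export
evalReport <- function(truth, scores, threshold = 0.5) {
    counts <- confusionCounts(truth, classifyProb(scores, threshold))
    m <- classificationMetrics(counts)
    auc <- if (length(unique(truth)) == 2L) rocAUC(truth, scores)
           else NA_real_
    new("EvalReport", counts = as.integer(counts) |>
            stats::setNames(c("TP", "FP", "TN", "FN")),
        acc = m[["ACC"]], sn = m[["Sn"]], sp = m[["Sp"]],
        mcc = m[["MCC"]], auc = auc)
}

#' Assign chains to cross-validation folds
#'
#' Chain-level assignment (never residue-level, so no chain contributes
#' residues to both the training and the test side of any fold):
#' chains are taken in decreasing length order, with ties broken by a
#' seeded shuffle, and each chain goes to the fold with the smallest
#' running residue total, yielding folds of almost equal residue size.
#'
#' @param chainLengths Named numeric vector: chain id -> chain length
#'   in residues.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling tie-breaking.
#' @return Named integer vector: chain id -> fold index in `1..k`.
#' @export
#' @examples
#' makeFolds(setNames(rep(50, 10), paste0("c", 1:10)), k = 5, seed = 1)
makeFolds <- function(chainLengths, k = 5L, seed = 1L) {
    n <- length(chainLengths)
    if (n < k) stop("input error: fewer chains (", n,
                    ") than folds (", k, ")")
    if (is.null(names(chainLengths)) || anyDuplicated(names(chainLengths)))
        stop("input error: chainLengths must have unique names")
    ord <- .withSeed(as.integer(seed), function()
        order(-chainLengths, sample.int(n)))
    totals <- numeric(k)
    fold <- integer(n)
    for (i in ord) {
        f <- which.min(totals)
        fold[i] <- f
        totals[f] <- totals[f] + chainLengths[i]
    }
    stats::setNames(fold, names(chainLengths))
}

#' Chain-level k-fold cross-validation
#'
#' For each fold, trains the specified classifier on the residues of
#' all chains outside the fold and predicts the residues of the chains
#' inside it.  Reports one [EvalReport-class] per fold plus a pooled
#' report over the concatenated test predictions (the pooled confusion
#' counts equal the sum of the per-fold counts).  A fold whose test
#' truth is single-class gets `NA` AUC and is flagged.
#'
#' @param datasetsByChain Named list of per-chain
#'   [LabeledDataset-class] objects.
#' @param spec A [ModelSpec-class].
#' @param folds Named integer vector from [makeFolds()]; every chain in
#'   `datasetsByChain` must be assigned.
#' @param threshold Classification threshold for the reports.
#' @return A list with elements `foldReports` (list of
#'   [EvalReport-class]), `pooled` (an [EvalReport-class]),
#'   `meanFoldAUC` (mean of the defined per-fold AUCs), `predictions`
#'   (a `data.frame` of chainId, position, fold, truth, prob) and
#'   `degenerateFolds` (indices of single-class test folds).
#' @export
crossValidate <- function(datasetsByChain, spec, folds,
                          threshold = 0.5) {
    stopifnot(is(spec, "ModelSpec"))
    chains <- names(datasetsByChain)
    if (is.null(chains) || !all(chains %in% names(folds)))
        stop("every chain needs a fold assignment")
    folds <- folds[chains]
    foldReports <- list()
    degenerate <- integer(0)
    pred <- list()
    for (f in sort(unique(folds))) {
        testChains <- chains[folds == f]
        trainChains <- chains[folds != f]
        model <- trainModel(
            assembleDatasets(datasetsByChain[trainChains]), spec)
        testSet <- assembleDatasets(datasetsByChain[testChains])
        ## leakage guard: no (chain, position) of the test set may
        ## appear in the training chains
        stopifnot(!any(testChains %in% trainChains))
        p <- predictProb(model, testSet)
        truth <- interfaceLabels(testSet)
        if (length(unique(truth)) < 2L)
            degenerate <- c(degenerate, f)
        foldReports[[as.character(f)]] <-
            evalReport(truth, p, threshold)
        pred[[as.character(f)]] <-
            cbind(provenance(testSet), fold = f, truth = truth,
                  prob = p)
    }
    predictions <- do.call(rbind, pred)
    rownames(predictions) <- NULL
    foldAUC <- vapply(foldReports, function(r) r@auc, numeric(1))
    list(foldReports = foldReports,
         pooled = evalReport(predictions$truth, predictions$prob,
                             threshold),
         meanFoldAUC = mean(foldAUC, na.rm = TRUE),
         predictions = predictions,
         degenerateFolds = degenerate)
}

#' Write an evaluation report as JSON or TSV
#'
#' @param report An [EvalReport-class].
#' @param file Output path; format chosen by extension (`.json` or
#'   anything else for TSV).
#' @return `file`, invisibly.
#' @export
writeReport <- function(report, file) {
    stopifnot(is(report, "EvalReport"))
    k <- reportCounts(report); m <- reportMetrics(report)
    if (grepl("\\.json$", file)) {
        jsonlite::write_json(c(as.list(k), as.list(m)), file,
                             auto_unbox = TRUE, digits = NA, na = "null")
    } else {
        d <- data.frame(metric = c(names(k), names(m)),
                        value = c(unname(k), unname(m)))
        utils::write.table(d, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(file)
}
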