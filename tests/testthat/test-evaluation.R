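test_that("confusion counts partition the positions and match a loop oracle", {
    expect_identical(confusionCounts(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                                     c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)),
                     c(TP = 4L, FP = 0L, TN = 6L, FN = 0L))
    expect_identical(confusionCounts(rep(0, 5), rep(1, 5))[["FP"]], 5L)
    set.seed(50)
    truth <- rbinom(50, 1, 0.3); pred <- rbinom(50, 1, 0.5)
    k <- confusionCounts(truth, pred)
    expect_identical(k, bruteConfusion(truth, pred))
    expect_identical(sum(k), 50L)
    expect_error(confusionCounts(c(0, 1), c(0, 1, 1)), "length")
})

test_that("metrics reproduce the closed-form values and conventions", {
    m <- classificationMetrics(c(TP = 4, FP = 0, TN = 6, FN = 0))
    expect_equal(unname(m), c(1, 1, 1, 1))

    m <- classificationMetrics(c(TP = 3, FP = 1, TN = 5, FN = 1))
    expect_equal(m[["ACC"]], 0.8)
    expect_equal(m[["Sn"]], 0.75)
    expect_equal(m[["Sp"]], 5 / 6)
    expect_equal(m[["MCC"]], 14 / 24)   # (15-1)/sqrt(6*6*4*4)

    ## no positive predictions -> MCC 0 by convention
    m <- classificationMetrics(c(TP = 0, FP = 0, TN = 8, FN = 2))
    expect_identical(m[["MCC"]], 0)
    ## no true positives at all -> Sn undefined
    m <- classificationMetrics(c(TP = 0, FP = 3, TN = 7, FN = 0))
    expect_true(is.na(m[["Sn"]]))
    expect_error(classificationMetrics(c(TP = 0, FP = 0, TN = 0,
                                         FN = 0)), "zero")
})

test_that("MCC symmetries hold on random confusion tables", {
    set.seed(60)
    for (i in 1:20) {
        k <- c(TP = sample(0:30, 1), FP = sample(0:30, 1),
               TN = sample(0:30, 1), FN = sample(0:30, 1))
        if (sum(k) == 0) next
        mcc <- classificationMetrics(k)[["MCC"]]
        expect_gte(mcc, -1); expect_lte(mcc, 1)
        ## swapping all predictions negates MCC (when defined both ways)
        flip <- c(TP = k[["FN"]], FP = k[["TN"]],
                  TN = k[["FP"]], FN = k[["TP"]])
        expect_equal(classificationMetrics(flip)[["MCC"]], -mcc,
                     tolerance = 1e-12)
        ## swapping the class roles leaves MCC unchanged
        swap <- c(TP = k[["TN"]], FP = k[["FN"]],
                  TN = k[["TP"]], FN = k[["FP"]])
        expect_equal(classificationMetrics(swap)[["MCC"]], mcc,
                     tolerance = 1e-12)
    }
})

test_that("AUC handles the canonical fixtures, ties and invariances", {
    expect_equal(rocAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)), 1)
    expect_equal(rocAUC(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
    truth <- c(1, 1, 0, 1, 0, 0)
    scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
    expect_equal(rocAUC(truth, scores), 8 / 9, tolerance = 1e-12)
    expect_equal(rocAUC(truth, scores), bruteAUC(truth, scores))
    expect_error(rocAUC(rep(1, 4), runif(4)), "both classes")

    set.seed(61)
    for (i in 1:10) {
        truth <- c(1, 0, rbinom(48, 1, 0.4))
        scores <- round(runif(50), 2)       # rounding induces ties
        a <- rocAUC(truth, scores)
        expect_equal(a, bruteAUC(truth, scores), tolerance = 1e-12)
        ## invariant under strictly monotone transforms
        expect_equal(rocAUC(truth, exp(3 * scores)), a,
                     tolerance = 1e-12)
        expect_equal(rocAUC(truth, scores),
                     pROC::auc(pROC::roc(truth, scores,
                                         quiet = TRUE,
                                         direction = "<"))[1],
                     tolerance = 1e-12)
    }
})

test_that("ROC points integrate to the rank-sum AUC", {
    set.seed(62)
    truth <- rbinom(80, 1, 0.35)
    scores <- round(runif(80), 2)
    pts <- rocPoints(truth, scores)
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(trap, rocAUC(truth, scores), tolerance = 1e-12)
})

test_that("fold assignment is balanced, seeded, and a partition", {
    lens <- setNames(rep(50, 10), paste0("c", 1:10))
    f <- makeFolds(lens, k = 5, seed = 1)
    expect_identical(as.vector(table(f)), rep(2L, 5))
    expect_identical(makeFolds(lens, k = 5, seed = 7),
                     makeFolds(lens, k = 5, seed = 7))

    set.seed(63)
    lens2 <- setNames(sample(40:400, 23), paste0("ch", 1:23))
    f2 <- makeFolds(lens2, k = 5, seed = 3)
    expect_setequal(names(f2), names(lens2))
    expect_identical(anyDuplicated(names(f2)), 0L)
    expect_true(all(f2 %in% 1:5))
    totals <- tapply(lens2[names(f2)], f2, sum)
    expect_lte(max(totals) / min(totals), 1.3)
    expect_error(makeFolds(lens[1:3], k = 5), "fewer chains")
})

test_that("chain-level CV pools correctly and never leaks test chains", {
    sim <- synthProfileDataset(8L, 30L, signalSpec(seed = 88L),
                               windowConfig(window = 11L))
    lens <- vapply(sim$datasetsByChain,
                   function(d) length(interfaceLabels(d)), numeric(1))
    folds <- makeFolds(lens, k = 4, seed = 2)
    cv <- crossValidate(sim$datasetsByChain,
                        modelSpec("RF100", seed = 2L), folds)
    ## pooled counts equal the sum of per-fold counts
    foldSum <- Reduce(`+`, lapply(cv$foldReports, reportCounts))
    expect_identical(foldSum, reportCounts(cv$pooled))
    ## every residue predicted exactly once, in its assigned fold
    pr <- cv$predictions
    key <- paste(pr$chainId, pr$position)
    expect_identical(anyDuplicated(key), 0L)
    expect_identical(nrow(pr), as.integer(sum(lens)))
    expect_identical(unname(folds[pr$chainId]), pr$fold)
    ## signal is recovered well above chance
    expect_gt(reportMetrics(cv$pooled)[["AUC"]], 0.8)
})

test_that("reports serialize to JSON and TSV", {
    r <- evalReport(c(1, 1, 0, 0, 1), c(0.9, 0.4, 0.2, 0.6, 0.8))
    fj <- withr::local_tempfile(fileext = ".json")
    writeReport(r, fj)
    j <- jsonlite::read_json(fj)
    expect_identical(j$TP, 2L)
    expect_equal(j$MCC, reportMetrics(r)[["MCC"]], tolerance = 1e-9)
    ft <- withr::local_tempfile(fileext = ".tsv")
    writeReport(r, ft)
    expect_identical(nrow(read.delim(ft)), 9L)
})
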