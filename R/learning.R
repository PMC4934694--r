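## Classifier training and prediction.  Model fitting is delegated to
## e1071 (SVM, naive Bayes) and randomForest; this module owns the
## specification, seeding, probability extraction and the SVMRBF+RF100
## consensus.

.featNames <- function(w) paste0("f", seq_len(w))

.asFeatures <- function(vectors) {
    if (is(vectors, "LabeledDataset")) vectors <- featureMatrix(vectors)
    if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
    colnames(vectors) <- .featNames(ncol(vectors))
    vectors
}

## run fn() under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, fn) {
    hasSeed <- exists(".Random.seed", envir = globalenv())
    if (hasSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (hasSeed) assign(".Random.seed", old,
                                envir = globalenv()))
    set.seed(seed)
    fn()
}

#' Train an interface-residue classifier
#'
#' Fits the classifier family named by the [ModelSpec-class]: Gaussian
#' naive Bayes (`NB`), a 100-tree random forest (`RF100`), a linear- or
#' RBF-kernel support vector machine (`SVML`, `SVMRBF`), or the
#' consensus (`CONSENSUS`), which trains both an SVMRBF and an RF100
#' member and averages their probabilities at prediction time.
#'
#' SVM defaults are cost 1 and, for the RBF kernel, gamma = 1 / feature
#' width (override via the spec's hyperparameters); probabilities come
#' from the standard sigmoid calibration fitted by the SVM library.
#' Features are assumed to lie in (0, 1) already (logistic-normalized
#' profiles), so no additional scaling is applied.  Training is
#' reproducible: the spec's seed fully determines the fit.
#'
#' @param dataset A [LabeledDataset-class] containing both classes.
#' @param spec A [ModelSpec-class].
#' @return A [ClassifierModel-class].
#' @export
#' @examples
#' ds <- synthProfileDataset(4L, 30L, signalSpec(seed = 1L))$dataset
#' m <- trainModel(ds, modelSpec("RF100", seed = 1L))
#' range(predictProb(m, ds))
trainModel <- function(dataset, spec) {
    stopifnot(is(dataset, "LabeledDataset"), is(spec, "ModelSpec"))
    x <- .asFeatures(featureMatrix(dataset))
    if (ncol(x) == 0L) stop("dimension error: zero-width feature matrix")
    if (nrow(x) == 0L) stop("training error: empty dataset")
    y <- factor(interfaceLabels(dataset), levels = c(0L, 1L))
    if (length(unique(y)) < 2L)
        stop("training error: both classes must be present")
    hp <- spec@hyperparams
    fit <- switch(spec@algorithm,
        NB = list(NB = .withSeed(spec@seed, function()
            e1071::naiveBayes(x = as.data.frame(x), y = y))),
        RF100 = list(RF100 = .withSeed(spec@seed, function()
            randomForest::randomForest(x = x, y = y, ntree = 100L))),
        SVML = list(SVML = .withSeed(spec@seed, function()
            e1071::svm(x = x, y = y, kernel = "linear",
                       cost = hp$cost %||% 1, scale = FALSE,
                       probability = TRUE))),
        SVMRBF = list(SVMRBF = .withSeed(spec@seed, function()
            e1071::svm(x = x, y = y, kernel = "radial",
                       cost = hp$cost %||% 1,
                       gamma = hp$gamma %||% (1 / ncol(x)),
                       scale = FALSE, probability = TRUE))),
        CONSENSUS = {
            sv <- trainModel(dataset, new("ModelSpec",
                algorithm = "SVMRBF", hyperparams = hp,
                seed = spec@seed))
            rf <- trainModel(dataset, new("ModelSpec",
                algorithm = "RF100", hyperparams = list(),
                seed = spec@seed))
            list(SVMRBF = sv, RF100 = rf)
        })
    new("ClassifierModel", spec = spec, fit = fit,
        featureWidth = ncol(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict per-residue interface probabilities
#'
#' @param model A trained [ClassifierModel-class].
#' @param vectors Feature matrix (or [LabeledDataset-class]) whose width
#'   matches the model's.
#' @return Numeric vector of interface probabilities in \[0, 1\], one
#'   per row.
#' @export
predictProb <- function(model, vectors) {
    stopifnot(is(model, "ClassifierModel"))
    x <- .asFeatures(vectors)
    if (ncol(x) != featureWidth(model))
        stop("dimension error: model expects ", featureWidth(model),
             " features, got ", ncol(x))
    if (algorithm(model) == "CONSENSUS")
        return(consensusPredict(model@fit, x))
    fit <- model@fit[[1]]
    p <- switch(algorithm(model),
        NB = stats::predict(fit, as.data.frame(x), type = "raw")[, "1"],
        RF100 = stats::predict(fit, x, type = "prob")[, "1"],
        SVML = ,
        SVMRBF = attr(stats::predict(fit, x, probability = TRUE),
                      "probabilities")[, "1"])
    unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Consensus of the SVMRBF and RF100 members
#'
#' Returns the elementwise arithmetic mean of the interface
#' probabilities of the RBF-kernel SVM and the 100-tree random forest.
#' The consensus probability therefore always lies between the two
#' member probabilities.
#'
#' @param members Named list with exactly the elements `SVMRBF` and
#'   `RF100`, each a trained [ClassifierModel-class] of that family
#'   (and equal feature widths).
#' @param vectors Feature matrix or [LabeledDataset-class].
#' @return Numeric vector of consensus probabilities.
#' @export
consensusPredict <- function(members, vectors) {
    if (!all(c("SVMRBF", "RF100") %in% names(members)))
        stop("configuration error: consensus needs members ",
             "'SVMRBF' and 'RF100'")
    (predictProb(members$SVMRBF, vectors) +
     predictProb(members$RF100, vectors)) / 2
}

#' Threshold probabilities into binary labels
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param threshold Classification threshold in \[0, 1\] (default 0.5).
#'   A residue is called an interface when its probability is greater
#'   than or equal to the threshold (ties go to the positive class).
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' classifyProb(c(0.2, 0.5, 0.9))
classifyProb <- function(probabilities, threshold = 0.5) {
    if (length(threshold) != 1L || is.na(threshold) ||
        threshold < 0 || threshold > 1)
        stop("parameter error: threshold must lie in [0, 1]")
    if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
        stop("probabilities must lie in [0, 1]")
    as.integer(probabilities >= threshold)
}

#' Save / load a trained classifier
#'
#' Models are serialized with an embedded format-version header and the
#' training [ModelSpec-class]; loading checks both.
#'
#' @param model A [ClassifierModel-class].
#' @param file Path of the model file.
#' @return `saveModel` returns `file` invisibly; `loadModel` returns
#'   the restored [ClassifierModel-class].
#' @export
saveModel <- function(model, file) {
    stopifnot(is(model, "ClassifierModel"))
    saveRDS(list(format = "RNAInterface-model", version = 1L,
                 spec = model@spec, fit = model@fit,
                 featureWidth = model@featureWidth),
            file)
    invisible(file)
}

#' @rdname saveModel
#' @export
loadModel <- function(file) {
    obj <- readRDS(file)
    if (!identical(obj$format, "RNAInterface-model"))
        stop("not a model file: ", file)
    if (obj$version > 1L)
        stop("model file version ", obj$version, " is newer than ",
             "this package supports")
    new("ClassifierModel", spec = obj$spec, fit = obj$fit,
        featureWidth = obj$featureWidth)
}
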