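#' @import methods
NULL

#' Canonical PSSM amino-acid column order
#'
#' The fixed 20-symbol column order used by PSI-BLAST ASCII PSSM files
#' (A R N D C Q E G H I L K M F P S T W Y V).  All score matrices in this
#' package use this column order.
#'
#' @return Character vector of the 20 one-letter amino-acid codes.
#' @export
#' @examples
#' pssmAlphabet()
pssmAlphabet <- function() {
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

## ---------------------------------------------------------------------------
## Structures
## ---------------------------------------------------------------------------

#' ComplexStructure: a parsed protein-RNA complex
#'
#' Holds the atoms of a protein-RNA complex as a flat table, one row per
#' atom, with per-residue identity (chain, author-order residue index,
#' one-letter code, protein/rna kind) and Cartesian coordinates in
#' angstroms, plus the crystallographic resolution when the record
#' states one.
#'
#' @slot id Structure identifier.
#' @slot atoms A `data.frame` with columns `chain`, `resIndex` (1-based
#'   position within its chain), `code` (one-letter residue code),
#'   `kind` (`"protein"` or `"rna"`), `element`, `atomName`, `x`, `y`, `z`.
#' @slot resolution Resolution in angstroms, or `NA_real_` when absent.
#'
#' @seealso [parseComplex()], [annotateInterfaces()], [synthComplex()]
#' @export
setClass("ComplexStructure",
    representation(id = "character", atoms = "data.frame",
                   resolution = "numeric"))

setValidity("ComplexStructure", function(object) {
    a <- object@atoms
    need <- c("chain", "resIndex", "code", "kind", "element",
              "atomName", "x", "y", "z")
    if (!all(need %in% names(a)))
        return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(a)) {
        if (!all(a$kind %in% c("protein", "rna")))
            return("atom kind must be 'protein' or 'rna'")
        if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
            return("atom coordinates must be finite")
        if (any(a$resIndex < 1L))
            return("residue indices are 1-based")
        ## a chain holds residues of one kind only
        kk <- tapply(a$kind, a$chain, function(k) length(unique(k)))
        if (any(kk > 1L))
            return("a chain may not mix protein and RNA residues")
    }
    if (length(object@resolution) != 1L)
        return("resolution must be a single number (possibly NA)")
    TRUE
})

#' InterfaceAnnotation: per-residue interface labels for one chain
#'
#' @slot chainId Chain identifier.
#' @slot sequence One-letter protein sequence of length L.
#' @slot labels Integer vector of length L; 1 marks an interface residue
#'   (some atom within the distance cutoff of any RNA atom), 0 otherwise.
#'
#' @seealso [annotateInterfaces()], [writeAnnotations()]
#' @export
setClass("InterfaceAnnotation",
    representation(chainId = "character", sequence = "character",
                   labels = "integer"))

setValidity("InterfaceAnnotation", function(object) {
    if (length(object@sequence) != 1L)
        return("sequence must be a single string")
    if (nchar(object@sequence) != length(object@labels))
        return("labels and sequence must have equal length")
    if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
        return("labels must be 0/1")
    TRUE
})

## ---------------------------------------------------------------------------
## Profiles
## ---------------------------------------------------------------------------

#' PSSMProfile: raw log-odds position-specific scoring matrix
#'
#' An L x 20 matrix of raw (integer-valued) log-odds scores for a query
#' sequence of length L, with columns in the canonical PSI-BLAST order
#' ([pssmAlphabet()]).  Optionally carries the number of database hits
#' PSI-BLAST used in the final search round.
#'
#' @slot sequence Query sequence (one-letter, length L).
#' @slot scores L x 20 numeric matrix of raw log-odds scores.
#' @slot nHits Number of hits used to build the profile, or `NA_real_`.
#'
#' @seealso [parsePSSM()], [pseudoProfile()], [normalizeLogistic()]
#' @export
setClass("PSSMProfile",
    representation(sequence = "character", scores = "matrix",
                   nHits = "numeric"))

setValidity("PSSMProfile", function(object) {
    L <- nchar(object@sequence)
    if (length(object@sequence) != 1L)
        return("sequence must be a single string")
    if (ncol(object@scores) != 20L)
        return("score matrix must have exactly 20 columns")
    if (nrow(object@scores) != L)
        return("score matrix must have one row per residue")
    if (!identical(colnames(object@scores), pssmAlphabet()))
        return("score columns must follow the canonical order A R N D ... V")
    if (length(object@nHits) != 1L)
        return("nHits must be a single number (possibly NA)")
    TRUE
})

#' NormalizedProfile: logistic-normalized PSSM
#'
#' The image of a [PSSMProfile-class] under the elementwise logistic map
#' `x -> 1 / (1 + exp(-x))`; every entry lies strictly in (0, 1), which
#' also makes the symmetrized Kullback-Leibler divergence well defined.
#'
#' @slot sequence Query sequence (one-letter, length L).
#' @slot values L x 20 numeric matrix with entries strictly in (0, 1).
#'
#' @seealso [normalizeLogistic()], [nssd()], [nkl()], [encodeChain()]
#' @export
setClass("NormalizedProfile",
    representation(sequence = "character", values = "matrix"))

setValidity("NormalizedProfile", function(object) {
    L <- nchar(object@sequence)
    if (nrow(object@values) != L || ncol(object@values) != 20L)
        return("values must be an L x 20 matrix")
    if (!identical(colnames(object@values), pssmAlphabet()))
        return("value columns must follow the canonical order A R N D ... V")
    v <- object@values
    if (length(v) && (any(v <= 0) || any(v >= 1)))
        return("all entries must lie strictly in (0, 1)")
    TRUE
})

## ---------------------------------------------------------------------------
## Encoding
## ---------------------------------------------------------------------------

#' WindowConfig: sliding-window encoding parameters
#'
#' @slot window Odd window width in residues (default 25).
#' @slot padValue Value filled into all 20 slots of window positions that
#'   fall outside the chain (default 0.5, the logistic image of a raw
#'   score of 0, i.e. the "no information" point).
#'
#' @seealso [windowConfig()], [encodeResidue()]
#' @export
setClass("WindowConfig",
    representation(window = "integer", padValue = "numeric"))

setValidity("WindowConfig", function(object) {
    w <- object@window
    if (length(w) != 1L || is.na(w) || w < 1L || w %% 2L == 0L)
        return("window must be a single odd integer >= 1")
    p <- object@padValue
    if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
        return("padValue must lie strictly in (0, 1)")
    TRUE
})

#' Create a window-encoding configuration
#'
#' @param window Odd window width in residues.  The default of 25 gives
#'   the target residue 12 sequence neighbours on each side and a
#'   25 x 20 = 500-dimensional feature vector.
#' @param padValue Padding value for out-of-chain window positions.
#' @return A [WindowConfig-class] object.
#' @export
#' @examples
#' windowConfig()
#' flankSize(windowConfig(window = 11L))
windowConfig <- function(window = 25L, padValue = 0.5) {
    new("WindowConfig", window = as.integer(window), padValue = padValue)
}

#' LabeledDataset: windowed feature vectors with interface labels
#'
#' One row per residue: a `window * 20`-dimensional feature vector (the
#' concatenated normalized-profile rows of the window), the binary
#' interface label, and provenance (chain id and 1-based position).
#'
#' @slot features N x (window * 20) numeric matrix.
#' @slot labels Integer 0/1 vector of length N.
#' @slot chainId Character vector of length N.
#' @slot position Integer vector of length N (1-based within chain).
#'
#' @seealso [encodeChain()], [assembleDatasets()], [crossValidate()]
#' @export
setClass("LabeledDataset",
    representation(features = "matrix", labels = "integer",
                   chainId = "character", position = "integer"))

setValidity("LabeledDataset", function(object) {
    n <- nrow(object@features)
    if (length(object@labels) != n || length(object@chainId) != n ||
        length(object@position) != n)
        return("features, labels, chainId and position must be aligned")
    if (n && !all(object@labels %in% c(0L, 1L)))
        return("labels must be 0/1")
    TRUE
})

## ---------------------------------------------------------------------------
## Learning
## ---------------------------------------------------------------------------

#' ModelSpec: classifier family, hyperparameters and seed
#'
#' @slot algorithm One of `"NB"` (Gaussian naive Bayes), `"RF100"`
#'   (random forest, 100 trees), `"SVML"` (linear-kernel SVM),
#'   `"SVMRBF"` (RBF-kernel SVM) or `"CONSENSUS"` (mean of the SVMRBF
#'   and RF100 probabilities).
#' @slot hyperparams Named list of algorithm hyperparameters.
#' @slot seed Integer seed making training reproducible.
#'
#' @seealso [modelSpec()], [trainModel()]
#' @export
setClass("ModelSpec",
    representation(algorithm = "character", hyperparams = "list",
                   seed = "integer"))

.KNOWN_ALGORITHMS <- c("NB", "RF100", "SVML", "SVMRBF", "CONSENSUS")

setValidity("ModelSpec", function(object) {
    if (length(object@algorithm) != 1L ||
        !object@algorithm %in% .KNOWN_ALGORITHMS)
        return(paste("algorithm must be one of:",
                     paste(.KNOWN_ALGORITHMS, collapse = ", ")))
    if (object@algorithm == "RF100") {
        nt <- object@hyperparams$ntree
        if (!is.null(nt) && nt != 100L)
            return("RF100 uses exactly 100 trees")
    }
    if (length(object@seed) != 1L || is.na(object@seed))
        return("seed must be a single integer")
    TRUE
})

#' Create a classifier specification
#'
#' @param algorithm Classifier family; see [ModelSpec-class].
#' @param seed Integer seed for reproducible training.
#' @param ... Hyperparameter overrides.  For the SVMs: `cost` (default 1)
#'   and, for the RBF kernel, `gamma` (default 1/feature width).
#' @return A [ModelSpec-class] object.
#' @export
#' @examples
#' modelSpec("SVMRBF", seed = 1L, cost = 2)
modelSpec <- function(algorithm = c("CONSENSUS", "SVMRBF", "RF100",
                                    "SVML", "NB"),
                      seed = 1L, ...) {
    algorithm <- match.arg(algorithm)
    new("ModelSpec", algorithm = algorithm, hyperparams = list(...),
        seed = as.integer(seed))
}

#' ClassifierModel: a trained interface-residue predictor
#'
#' @slot spec The [ModelSpec-class] the model was trained under.
#' @slot fit Named list of fitted member models (one entry, or two for
#'   the consensus).
#' @slot featureWidth Width of the training feature vectors; prediction
#'   requires inputs of the same width.
#'
#' @seealso [trainModel()], [predictProb()]
#' @export
setClass("ClassifierModel",
    representation(spec = "ModelSpec", fit = "list",
                   featureWidth = "integer"))

## ---------------------------------------------------------------------------
## Evaluation
## ---------------------------------------------------------------------------

#' EvalReport: confusion counts and summary metrics
#'
#' @slot counts Named integer vector with elements `TP`, `FP`, `TN`, `FN`.
#' @slot acc Accuracy (TP+TN)/total.
#' @slot sn Sensitivity TP/(TP+FN); `NA` when no positives exist.
#' @slot sp Specificity TN/(TN+FP); `NA` when no negatives exist.
#' @slot mcc Matthews correlation coefficient; 0 by convention when any
#'   denominator factor vanishes.
#' @slot auc Area under the ROC curve; `NA` when undefined (single-class
#'   truth or thresholded labels only).
#'
#' @seealso [evalReport()], [classificationMetrics()], [rocAUC()]
#' @export
setClass("EvalReport",
    representation(counts = "integer", acc = "numeric", sn = "numeric",
                   sp = "numeric", mcc = "numeric", auc = "numeric"))

setValidity("EvalReport", function(object) {
    if (!identical(names(object@counts), c("TP", "FP", "TN", "FN")))
        return("counts must be named TP, FP, TN, FN")
    if (any(object@counts < 0L))
        return("confusion counts must be non-negative")
    TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ComplexStructure", function(object) {
    a <- object@atoms
    pc <- unique(a$chain[a$kind == "protein"])
    rc <- unique(a$chain[a$kind == "rna"])
    cat("ComplexStructure '", object@id, "': ",
        length(pc), " protein chain(s), ", length(rc), " RNA chain(s), ",
        nrow(a), " atoms; resolution ",
        ifelse(is.na(object@resolution), "unknown",
               sprintf("%.2f A", object@resolution)), "\n", sep = "")
})

setMethod("show", "InterfaceAnnotation", function(object) {
    cat("InterfaceAnnotation chain '", object@chainId, "': L=",
        nchar(object@sequence), ", ", sum(object@labels),
        " interface residue(s)\n", sep = "")
})

setMethod("show", "PSSMProfile", function(object) {
    cat("PSSMProfile: L=", nchar(object@sequence), ", 20 columns",
        if (!is.na(object@nHits)) sprintf(", %d hits", object@nHits),
        "\n", sep = "")
})

setMethod("show", "NormalizedProfile", function(object) {
    cat("NormalizedProfile: L=", nchar(object@sequence),
        ", entries in (0,1)\n", sep = "")
})

setMethod("show", "LabeledDataset", function(object) {
    cat("LabeledDataset: ", nrow(object@features), " residues x ",
        ncol(object@features), " features; ",
        sum(object@labels == 1L), " interface / ",
        sum(object@labels == 0L), " non-interface; ",
        length(unique(object@chainId)), " chain(s)\n", sep = "")
})

setMethod("show", "ModelSpec", function(object) {
    cat("ModelSpec: ", object@algorithm, " (seed ", object@seed, ")\n",
        sep = "")
})

setMethod("show", "ClassifierModel", function(object) {
    cat("ClassifierModel: ", object@spec@algorithm, ", ",
        object@featureWidth, " features\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
    k <- object@counts
    cat(sprintf(
        "EvalReport: TP=%d FP=%d TN=%d FN=%d | ACC=%.3f Sn=%s Sp=%s MCC=%.3f AUC=%s\n",
        k["TP"], k["FP"], k["TN"], k["FN"], object@acc,
        ifelse(is.na(object@sn), "NA", sprintf("%.3f", object@sn)),
        ifelse(is.na(object@sp), "NA", sprintf("%.3f", object@sp)),
        object@mcc,
        ifelse(is.na(object@auc), "NA", sprintf("%.3f", object@auc))))
})
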