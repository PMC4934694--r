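## Accessor generics.  Slots are never read directly by user code.

#' @rdname ComplexStructure-class
#' @param x An object.
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname ComplexStructure-class
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname ComplexStructure-class
#' @param kind `"protein"` or `"rna"`.
#' @export
setGeneric("chainIds", function(x, kind = c("protein", "rna"))
    standardGeneric("chainIds"))
#' @rdname ComplexStructure-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname ComplexStructure-class
#' @export
setGeneric("chainSequences", function(x, kind = c("protein", "rna"))
    standardGeneric("chainSequences"))

#' @rdname InterfaceAnnotation-class
#' @param x An object.
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname InterfaceAnnotation-class
#' @export
setGeneric("residueSequence", function(x) standardGeneric("residueSequence"))
#' @rdname InterfaceAnnotation-class
#' @export
setGeneric("interfaceLabels", function(x) standardGeneric("interfaceLabels"))

#' @rdname PSSMProfile-class
#' @param x An object.
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname PSSMProfile-class
#' @export
setGeneric("nHits", function(x) standardGeneric("nHits"))
#' @rdname NormalizedProfile-class
#' @param x An object.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname WindowConfig-class
#' @param x An object.
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))
#' @rdname WindowConfig-class
#' @export
setGeneric("flankSize", function(x) standardGeneric("flankSize"))
#' @rdname WindowConfig-class
#' @export
setGeneric("padValue", function(x) standardGeneric("padValue"))

#' @rdname LabeledDataset-class
#' @param x An object.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname LabeledDataset-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ModelSpec-class
#' @param x An object.
#' @export
setGeneric("algorithm", function(x) standardGeneric("algorithm"))
#' @rdname ClassifierModel-class
#' @param x An object.
#' @export
setGeneric("featureWidth", function(x) standardGeneric("featureWidth"))

#' @rdname EvalReport-class
#' @param x An object.
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))
#' @rdname EvalReport-class
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))

## ---------------------------------------------------------------------------
## Accessor methods
## ---------------------------------------------------------------------------

#' @rdname ComplexStructure-class
setMethod("structureId", "ComplexStructure", function(x) x@id)

#' @rdname ComplexStructure-class
setMethod("resolution", "ComplexStructure", function(x) x@resolution)

#' @rdname ComplexStructure-class
setMethod("atomTable", "ComplexStructure", function(x) x@atoms)

#' @rdname ComplexStructure-class
setMethod("chainIds", "ComplexStructure", function(x, kind) {
    kind <- match.arg(kind, c("protein", "rna"))
    unique(x@atoms$chain[x@atoms$kind == kind])
})

#' @rdname ComplexStructure-class
setMethod("chainSequences", "ComplexStructure", function(x, kind) {
    kind <- match.arg(kind, c("protein", "rna"))
    a <- x@atoms[x@atoms$kind == kind, , drop = FALSE]
    if (!nrow(a)) return(setNames(character(0), character(0)))
    res <- unique(a[, c("chain", "resIndex", "code")])
    vapply(split(res, factor(res$chain, levels = unique(res$chain))),
           function(d) paste(d$code[order(d$resIndex)], collapse = ""),
           character(1))
})

#' @rdname InterfaceAnnotation-class
setMethod("chainId", "InterfaceAnnotation", function(x) x@chainId)

#' @rdname InterfaceAnnotation-class
setMethod("residueSequence", "InterfaceAnnotation", function(x) x@sequence)

#' @rdname InterfaceAnnotation-class
setMethod("interfaceLabels", "InterfaceAnnotation", function(x) x@labels)

#' @rdname PSSMProfile-class
setMethod("residueSequence", "PSSMProfile", function(x) x@sequence)

#' @rdname PSSMProfile-class
setMethod("pssmScores", "PSSMProfile", function(x) x@scores)

#' @rdname PSSMProfile-class
setMethod("nHits", "PSSMProfile", function(x) x@nHits)

#' @rdname NormalizedProfile-class
setMethod("residueSequence", "NormalizedProfile", function(x) x@sequence)

#' @rdname NormalizedProfile-class
setMethod("profileValues", "NormalizedProfile", function(x) x@values)

#' @rdname WindowConfig-class
setMethod("windowSize", "WindowConfig", function(x) x@window)

#' @rdname WindowConfig-class
setMethod("flankSize", "WindowConfig", function(x) (x@window - 1L) %/% 2L)

#' @rdname WindowConfig-class
setMethod("padValue", "WindowConfig", function(x) x@padValue)

#' @rdname LabeledDataset-class
setMethod("featureMatrix", "LabeledDataset", function(x) x@features)

#' @rdname LabeledDataset-class
setMethod("interfaceLabels", "LabeledDataset", function(x) x@labels)

#' @rdname LabeledDataset-class
setMethod("provenance", "LabeledDataset", function(x)
    data.frame(chainId = x@chainId, position = x@position))

#' @rdname ModelSpec-class
setMethod("algorithm", "ModelSpec", function(x) x@algorithm)

#' @rdname ClassifierModel-class
setMethod("algorithm", "ClassifierModel", function(x) x@spec@algorithm)

#' @rdname ClassifierModel-class
setMethod("featureWidth", "ClassifierModel", function(x) x@featureWidth)

#' @rdname EvalReport-class
setMethod("reportCounts", "EvalReport", function(x) x@counts)

#' @rdname EvalReport-class
setMethod("reportMetrics", "EvalReport", function(x)
    c(ACC = x@acc, Sn = x@sn, Sp = x@sp, MCC = x@mcc, AUC = x@auc))
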