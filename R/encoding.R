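## Window encoding: normalized profile rows -> fixed-width feature
## vectors, one per residue, with terminus padding.

#' Encode one residue as a windowed feature vector
#'
#' Concatenates the 20-value normalized-profile rows of the window
#' centred on `position` (positions `position - flank` through
#' `position + flank`).  Window positions falling outside the chain
#' contribute the padding value in all 20 slots.  With the default
#' 25-residue window the vector has 25 x 20 = 500 entries, and entries
#' 241..260 are exactly the profile row of the target residue.
#'
#' @param profile A [NormalizedProfile-class].
#' @param position 1-based target residue position.
#' @param config A [WindowConfig-class] (default: 25-residue window,
#'   padding 0.5).
#' @return Numeric vector of length `windowSize(config) * 20`.
#' @export
#' @examples
#' p <- normalizeLogistic(pseudoProfile("ACDEFGHIK"))
#' length(encodeResidue(p, 5L))
encodeResidue <- function(profile, position, config = windowConfig()) {
    stopifnot(is(profile, "NormalizedProfile"), is(config, "WindowConfig"))
    v <- profileValues(profile)
    L <- nrow(v)
    if (position < 1L || position > L)
        stop("index error: position ", position,
             " outside chain of length ", L)
    flank <- flankSize(config)
    idx <- (position - flank):(position + flank)
    out <- matrix(padValue(config), length(idx), 20L)
    inside <- idx >= 1L & idx <= L
    out[inside, ] <- v[idx[inside], , drop = FALSE]
    as.vector(t(out))
}

#' Encode every residue of a chain
#'
#' @param profile A [NormalizedProfile-class] for the chain.
#' @param annotation The chain's [InterfaceAnnotation-class]; its
#'   sequence must equal the profile's.
#' @param config A [WindowConfig-class].
#' @return A [LabeledDataset-class] with one row per residue, labels
#'   copied from the annotation, and (chain, position) provenance.
#' @export
#' @examples
#' ann <- new("InterfaceAnnotation", chainId = "A",
#'            sequence = "ACDEF", labels = c(0L, 1L, 0L, 0L, 1L))
#' encodeChain(normalizeLogistic(pseudoProfile("ACDEF")), ann)
encodeChain <- function(profile, annotation, config = windowConfig()) {
    stopifnot(is(profile, "NormalizedProfile"),
              is(annotation, "InterfaceAnnotation"))
    if (!identical(residueSequence(profile), residueSequence(annotation)))
        stop("alignment error: profile and annotation sequences differ")
    L <- nchar(residueSequence(profile))
    feats <- t(vapply(seq_len(L),
                      function(i) encodeResidue(profile, i, config),
                      numeric(windowSize(config) * 20L)))
    new("LabeledDataset", features = feats,
        labels = interfaceLabels(annotation),
        chainId = rep(chainId(annotation), L),
        position = seq_len(L))
}

#' Row-concatenate labelled datasets
#'
#' @param datasets List of [LabeledDataset-class] with identical feature
#'   widths.
#' @return A single [LabeledDataset-class]; provenance is preserved and
#'   label counts are the sums of the inputs'.
#' @export
assembleDatasets <- function(datasets) {
    stopifnot(length(datasets) >= 1L)
    widths <- vapply(datasets, function(d) ncol(featureMatrix(d)),
                     integer(1))
    if (length(unique(widths)) != 1L)
        stop("dimension error: feature widths differ (",
             paste(unique(widths), collapse = ", "), ")")
    new("LabeledDataset",
        features = do.call(rbind, lapply(datasets, featureMatrix)),
        labels = unlist(lapply(datasets, interfaceLabels),
                        use.names = FALSE),
        chainId = unlist(lapply(datasets, function(d)
            provenance(d)$chainId), use.names = FALSE),
        position = unlist(lapply(datasets, function(d)
            provenance(d)$position), use.names = FALSE))
}

#' Write a labelled dataset as TSV
#'
#' Columns: `chainId`, `position`, the feature columns (`f1` ...), and
#' `label`.
#'
#' @param dataset A [LabeledDataset-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeDataset <- function(dataset, file) {
    stopifnot(is(dataset, "LabeledDataset"))
    f <- featureMatrix(dataset)
    colnames(f) <- paste0("f", seq_len(ncol(f)))
    d <- cbind(provenance(dataset), as.data.frame(f),
               label = interfaceLabels(dataset))
    utils::write.table(d, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a labelled dataset written by [writeDataset()]
#'
#' @param file TSV path.
#' @return A [LabeledDataset-class].
#' @export
readDataset <- function(file) {
    d <- utils::read.table(file, sep = "\t", header = TRUE,
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
    fcols <- grep("^f[0-9]+$", names(d))
    new("LabeledDataset",
        features = as.matrix(d[, fcols, drop = FALSE]),
        labels = as.integer(d$label),
        chainId = as.character(d$chainId),
        position = as.integer(d$position))
}
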