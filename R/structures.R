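## Structure handling: parsing protein-RNA complexes, distance-based
## interface annotation, and benchmark-style dataset admission filters.

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## common nonstandard amino acids seen as HETATM in protein chains;
## mapped to 'X' so sequence and label lengths stay aligned
.AA_NONSTANDARD <- c("MSE", "SEC", "PYL", "CSO", "PTR", "SEP", "TPO",
                     "HYP", "MLY", "M3L", "KCX", "LLP", "PCA")

.RNA_CODES <- c("A", "C", "G", "U")

#' Parse a protein-RNA complex from PDB-format text
#'
#' Reads ATOM/HETATM records (delegating record parsing to
#' [bio3d::read.pdb()]) and the `REMARK 2` resolution line, classifies
#' residues as protein or RNA, and returns a [ComplexStructure-class].
#'
#' Standard amino acids are mapped to their one-letter codes;
#' nonstandard amino acids (including HETATM residues such as MSE) are
#' mapped to `"X"` and kept in place so sequence and label lengths stay
#' aligned with the structure.  RNA residues are the `A`/`C`/`G`/`U`
#' nucleotides.  Waters, ions, DNA and other ligands are dropped.  Only
#' the first alternate location of each atom is kept; residues follow
#' the author's chain order.  Chains mixing residue kinds keep their
#' majority kind (minority residues are dropped with a warning).
#'
#' @param text PDB-format text: a single string or a character vector of
#'   lines.
#' @param id Structure identifier to record (default `"complex"`).
#' @return A [ComplexStructure-class].
#' @export
#' @examples
#' cx <- synthComplex(10L, c(3L, 7L), seed = 1L)
#' txt <- writePDB(cx)
#' parseComplex(txt, id = "toy")
parseComplex <- function(text, id = "complex") {
    if (length(text) == 1L)
        text <- strsplit(text, "\n", fixed = TRUE)[[1]]
    if (!any(grepl("^(ATOM  |HETATM)", text)))
        stop("no ATOM/HETATM records found: not PDB-format text")
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(text, tf)
    pdb <- tryCatch(bio3d::read.pdb(tf, verbose = FALSE),
                    error = function(e)
                        stop("unparseable PDB text: ", conditionMessage(e)))
    at <- pdb$atom
    ## first altloc only
    at <- at[is.na(at$alt) | at$alt == "" | at$alt == "A", , drop = FALSE]

    resid <- toupper(trimws(at$resid))
    kind <- rep(NA_character_, nrow(at))
    code <- rep(NA_character_, nrow(at))
    isAA <- resid %in% names(.AA3TO1)
    kind[isAA] <- "protein"
    code[isAA] <- .AA3TO1[resid[isAA]]
    isNonstd <- !isAA & (resid %in% .AA_NONSTANDARD |
                         (at$type == "ATOM" & nchar(resid) == 3L))
    kind[isNonstd] <- "protein"
    code[isNonstd] <- "X"
    isRNA <- is.na(kind) & resid %in% .RNA_CODES
    kind[isRNA] <- "rna"
    code[isRNA] <- tolower(resid[isRNA])
    keep <- !is.na(kind)
    at <- at[keep, , drop = FALSE]
    kind <- kind[keep]; code <- code[keep]

    if (!nrow(at))
        stop("empty complex: no protein or RNA residues")

    chain <- ifelse(is.na(at$chain) | at$chain == "", "_", at$chain)
    ## majority kind per chain; minority residues dropped
    for (ch in unique(chain)) {
        i <- chain == ch
        kk <- table(kind[i])
        if (length(kk) > 1L) {
            major <- names(kk)[which.max(kk)]
            drop <- i & kind != major
            warning("chain ", ch, ": dropping ", sum(drop),
                    " atom(s) of minority kind")
            at <- at[!drop, , drop = FALSE]
            kind <- kind[!drop]; code <- code[!drop]
            chain <- chain[!drop]
        }
    }
    if (!any(kind == "protein"))
        stop("empty complex: structure has no protein chains")

    insert <- ifelse(is.na(at$insert), "", at$insert)
    resKey <- paste(chain, at$resno, insert, sep = "|")
    resIndex <- integer(nrow(at))
    for (ch in unique(chain)) {
        i <- which(chain == ch)
        ## author order: record order of first atom of each residue
        first <- !duplicated(resKey[i])
        lev <- resKey[i][first]
        resIndex[i] <- match(resKey[i], lev)
    }

    elem <- if ("elesy" %in% names(at)) trimws(at$elesy) else ""
    elem[is.na(elem) | elem == ""] <-
        substr(trimws(at$elety[is.na(elem) | elem == ""]), 1L, 1L)

    atoms <- data.frame(chain = chain, resIndex = resIndex, code = code,
                        kind = kind, element = elem,
                        atomName = trimws(at$elety),
                        x = at$x, y = at$y, z = at$z,
                        stringsAsFactors = FALSE)
    new("ComplexStructure", id = id, atoms = atoms,
        resolution = .parseResolution(text))
}

.parseResolution <- function(lines) {
    rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (!length(rl)) return(NA_real_)
    rest <- sub("^REMARK   2 RESOLUTION\\.?", "", rl[1])
    m <- regmatches(rest, regexpr("[0-9]+\\.?[0-9]*", rest))
    if (!length(m)) NA_real_ else as.numeric(m)
}

#' Annotate interface residues of every protein chain
#'
#' A protein residue is an interface residue when at least one of its
#' atoms lies within `cutoff` angstroms (Euclidean, boundary inclusive)
#' of any atom of any RNA chain in the complex.  All recorded atoms
#' participate, hydrogens included.  The result is independent of atom
#' and chain ordering.
#'
#' @param complex A [ComplexStructure-class].
#' @param cutoff Distance cutoff in angstroms (default 5.0).
#' @return A list of [InterfaceAnnotation-class], one per protein chain.
#'   If the complex has no RNA chains, all labels are 0 (with a warning).
#' @export
#' @examples
#' cx <- synthComplex(10L, c(3L, 7L), seed = 1L)
#' ann <- annotateInterfaces(cx)[[1]]
#' which(interfaceLabels(ann) == 1L)
annotateInterfaces <- function(complex, cutoff = 5.0) {
    stopifnot(is(complex, "ComplexStructure"), cutoff > 0)
    a <- atomTable(complex)
    prot <- a[a$kind == "protein", , drop = FALSE]
    if (!nrow(prot)) stop("complex has no protein chains")
    rna <- a[a$kind == "rna", , drop = FALSE]
    noRNA <- nrow(rna) == 0L
    if (noRNA)
        warning("complex has no RNA chains; all labels set to 0")
    rcoord <- as.matrix(rna[, c("x", "y", "z")])

    lapply(unique(prot$chain), function(ch) {
        p <- prot[prot$chain == ch, , drop = FALSE]
        L <- max(p$resIndex)
        seqv <- character(L)
        seqv[p$resIndex[!duplicated(p$resIndex)]] <-
            p$code[!duplicated(p$resIndex)]
        labels <- integer(L)
        if (!noRNA) {
            pc <- as.matrix(p[, c("x", "y", "z")])
            ## squared-distance matrix protein atoms x RNA atoms
            d2 <- matrix(rowSums(pc^2), nrow(pc), nrow(rcoord)) +
                  matrix(rowSums(rcoord^2), nrow(pc), nrow(rcoord),
                         byrow = TRUE) - 2 * pc %*% t(rcoord)
            atomMin <- apply(d2, 1L, min)
            resMin <- tapply(atomMin, p$resIndex, min)
            hit <- as.integer(names(resMin))[sqrt(pmax(resMin, 0)) <= cutoff]
            labels[hit] <- 1L
        }
        new("InterfaceAnnotation", chainId = ch,
            sequence = paste(seqv, collapse = ""), labels = labels)
    })
}

#' Apply benchmark admission criteria to protein chains
#'
#' Retains protein chains from complexes whose structure resolution is
#' strictly below `minResolution` angstroms, whose chain length is at
#' least `minProteinLen` residues, that are bound to at least one RNA
#' chain of `minRnaLen` or more nucleotides, and that carry at least
#' `minInterfaces` interface residues at the given distance `cutoff`.
#' Chains are tested in that order and counted against the first
#' criterion they fail; complexes without resolution metadata are
#' rejected with reason `"unknown_resolution"`.
#'
#' @param complexes A list of [ComplexStructure-class].
#' @param minResolution Maximum (exclusive) resolution in angstroms.
#' @param minProteinLen Minimum protein chain length (residues).
#' @param minRnaLen Minimum RNA chain length (nucleotides).
#' @param minInterfaces Minimum number of interface residues per chain.
#' @param cutoff Interface distance cutoff in angstroms.
#' @return A list with elements `annotations` (named list of
#'   [InterfaceAnnotation-class] for the admitted chains, names
#'   `"<structure id>_<chain>"`) and `rejections` (named integer vector
#'   of per-criterion rejection counts).
#' @export
filterDataset <- function(complexes, minResolution = 3.5,
                          minProteinLen = 40L, minRnaLen = 5L,
                          minInterfaces = 3L, cutoff = 5.0) {
    kept <- list()
    rej <- c(unknown_resolution = 0L, resolution = 0L,
             protein_length = 0L, rna_length = 0L, interfaces = 0L)
    for (cx in complexes) {
        stopifnot(is(cx, "ComplexStructure"))
        anns <- suppressWarnings(annotateInterfaces(cx, cutoff = cutoff))
        rnaLens <- nchar(chainSequences(cx, "rna"))
        res <- resolution(cx)
        for (ann in anns) {
            if (is.na(res)) {
                rej["unknown_resolution"] <- rej["unknown_resolution"] + 1L
            } else if (res >= minResolution) {
                rej["resolution"] <- rej["resolution"] + 1L
            } else if (nchar(residueSequence(ann)) < minProteinLen) {
                rej["protein_length"] <- rej["protein_length"] + 1L
            } else if (!length(rnaLens) || max(rnaLens) < minRnaLen) {
                rej["rna_length"] <- rej["rna_length"] + 1L
            } else if (sum(interfaceLabels(ann)) < minInterfaces) {
                rej["interfaces"] <- rej["interfaces"] + 1L
            } else {
                kept[[paste0(structureId(cx), "_", chainId(ann))]] <- ann
            }
        }
    }
    list(annotations = kept, rejections = rej)
}

#' Greedy sequence-identity redundancy filter
#'
#' A simple longest-first greedy pass: sequences are visited in order of
#' decreasing length (ties keep input order) and a sequence is kept only
#' if its pairwise identity to every sequence already kept is at most
#' `maxIdentity`.  Identity is the number of identical aligned positions
#' divided by the global alignment length (gaps included), with the
#' alignment computed by [Biostrings::pairwiseAlignment()] under
#' BLOSUM62 scoring (gap opening 10, extension 0.5).  This is a
#' deterministic approximation of the similarity-clustering tools
#' (CD-HIT and relatives) used to build non-redundant benchmark sets,
#' not a reimplementation of them.
#'
#' @param sequences Character vector of protein sequences (optionally
#'   named).
#' @param maxIdentity Maximum allowed pairwise identity fraction
#'   (default 0.30).
#' @return The kept subset of `sequences`, in input order.
#' @export
#' @examples
#' greedyIdentityFilter(c(a = "MKTAYIAKQR", b = "MKTAYIAKQR"))
greedyIdentityFilter <- function(sequences, maxIdentity = 0.30) {
    stopifnot(length(sequences) >= 1L, maxIdentity >= 0, maxIdentity <= 1)
    ord <- order(-nchar(sequences))   # stable: ties keep input order
    keptIdx <- integer(0)
    for (i in ord) {
        ok <- all(vapply(keptIdx, function(j)
            .pairIdentity(sequences[i], sequences[j]) <= maxIdentity,
            logical(1)))
        if (ok) keptIdx <- c(keptIdx, i)
    }
    sequences[sort(keptIdx)]
}

.pairIdentity <- function(s1, s2) {
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(s1), Biostrings::AAString(s2),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5)
    Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Write interface annotations
#'
#' Two plain-text layouts are supported: the benchmark label style (per
#' chain: a `>` header line, the sequence line, and a same-length 0/1
#' label string) and a BED-like TSV (`chain`, 1-based `position`,
#' `residue`, `label`).
#'
#' @param annotations List of [InterfaceAnnotation-class].
#' @param file Output path.
#' @param format `"labels"` (benchmark style) or `"tsv"`.
#' @return `file`, invisibly.
#' @seealso [readAnnotations()]
#' @export
writeAnnotations <- function(annotations, file,
                             format = c("labels", "tsv")) {
    format <- match.arg(format)
    if (format == "labels") {
        lines <- unlist(lapply(annotations, function(a)
            c(paste0(">", chainId(a)), residueSequence(a),
              paste(interfaceLabels(a), collapse = ""))))
        writeLines(lines, file)
    } else {
        rows <- do.call(rbind, lapply(annotations, function(a)
            data.frame(chain = chainId(a),
                       position = seq_len(nchar(residueSequence(a))),
                       residue = strsplit(residueSequence(a), "")[[1]],
                       label = interfaceLabels(a))))
        utils::write.table(rows, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(file)
}

#' Read benchmark-style interface annotations
#'
#' Parses the per-chain header / sequence / binary-label-string layout
#' written by [writeAnnotations()] (and used by the published benchmark
#' label files).
#'
#' @param file Path to a label file.
#' @return Named list of [InterfaceAnnotation-class].
#' @export
readAnnotations <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no '>' headers found in ", file)
    out <- list()
    for (h in hdr) {
        if (h + 2L > length(lines))
            stop("truncated record at line ", h)
        id <- sub("^>\\s*", "", lines[h])
        seqv <- trimws(lines[h + 1L])
        lab <- trimws(lines[h + 2L])
        if (nchar(seqv) != nchar(lab))
            stop("sequence/label length mismatch for ", id)
        out[[id]] <- new("InterfaceAnnotation", chainId = id,
                         sequence = seqv,
                         labels = as.integer(strsplit(lab, "")[[1]]))
    }
    out
}
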