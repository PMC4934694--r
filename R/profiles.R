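## Evolutionary profiles: PSI-BLAST invocation, ASCII PSSM parsing and
## writing, logistic normalization, and the two profile distance metrics.

#' Generate a PSSM profile with PSI-BLAST
#'
#' Runs the external `psiblast` binary for `iterations` rounds of search
#' against a formatted BLAST database, with `evalue` used both as the
#' reporting threshold and as the profile inclusion threshold, and
#' parses the ASCII PSSM of the final round.  The number of hits found
#' in the final round is recorded on the returned profile.
#'
#' @param sequence Query protein sequence (one-letter string).
#' @param databasePath Path to a BLAST protein database (as produced by
#'   `makeblastdb`).
#' @param iterations Number of PSI-BLAST iterations (default 3).
#' @param evalue E-value threshold (default 0.001).
#' @param threads Number of search threads (default 1).
#' @param binary Name or path of the psiblast executable.
#' @param dryRun If `TRUE`, do not run anything; return the command line
#'   that would be executed (a character string).
#' @return A [PSSMProfile-class] (or the command string when
#'   `dryRun = TRUE`).  With zero hits PSI-BLAST still emits a
#'   substitution-matrix-backed PSSM, returned with `nHits = 0`.
#' @seealso [pseudoProfile()] for an offline fallback.
#' @export
runPsiblast <- function(sequence, databasePath, iterations = 3L,
                        evalue = 0.001, threads = 1L,
                        binary = "psiblast", dryRun = FALSE) {
    qf <- tempfile(fileext = ".fasta")
    pf <- tempfile(fileext = ".pssm")
    rf <- tempfile(fileext = ".tab")
    args <- c("-query", qf, "-db", databasePath,
              "-num_iterations", iterations,
              "-evalue", format(evalue, scientific = FALSE),
              "-inclusion_ethresh", format(evalue, scientific = FALSE),
              "-num_threads", threads,
              "-out_ascii_pssm", pf, "-outfmt", "7", "-out", rf)
    if (dryRun)
        return(paste(c(binary, args), collapse = " "))
    if (Sys.which(binary) == "")
        stop("tool unavailable: '", binary, "' not found on PATH")
    on.exit(unlink(c(qf, pf, rf)))
    writeLines(c(">query", sequence), qf)
    status <- suppressWarnings(
        system2(binary, shQuote(args), stdout = FALSE, stderr = FALSE))
    if (status != 0L)
        stop("psiblast failed with exit status ", status)
    if (!file.exists(pf)) {
        ## a search with zero hits computes no PSSM at all; fall back
        ## to the substitution-matrix profile of the query
        prof <- pseudoProfile(sequence)
        prof@nHits <- 0
        return(prof)
    }
    prof <- parsePSSM(readLines(pf))
    prof@nHits <- .lastRoundHits(readLines(rf))
    validObject(prof)
    prof
}

.lastRoundHits <- function(reportLines) {
    m <- regmatches(reportLines,
                    regexpr("^# [0-9]+ hits found", reportLines))
    m <- unlist(m)
    if (!length(m)) return(NA_real_)
    as.numeric(sub("^# ([0-9]+) hits found", "\\1", m[length(m)]))
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the ASCII matrix layout written by PSI-BLAST's
#' `-out_ascii_pssm` option (and by [writePSSM()]): a header naming the
#' 20 amino-acid columns followed by one line per residue holding the
#' position, the residue letter and at least 20 integer log-odds scores
#' (the weighted-percentage columns, when present, are ignored).
#'
#' @param text PSSM text: a single string or character vector of lines.
#' @return A [PSSMProfile-class] with integer-valued scores.
#' @export
#' @examples
#' p <- pseudoProfile("ACD")
#' identical(pssmScores(parsePSSM(writePSSM(p))), pssmScores(p))
parsePSSM <- function(text) {
    if (length(text) == 1L)
        text <- strsplit(text, "\n", fixed = TRUE)[[1]]
    toks <- lapply(text, function(l) strsplit(trimws(l), "\\s+")[[1]])
    ## header: the line whose tokens start with the 20 column letters
    hdr <- which(vapply(toks, function(tk)
        length(tk) >= 20L && identical(tk[1:20], pssmAlphabet()),
        logical(1)))
    if (!length(hdr))
        stop("format error: no PSSM column header found")
    rows <- list(); letters1 <- character(0)
    for (i in seq(hdr[1] + 1L, length(text))) {
        tk <- toks[[i]]
        if (!length(tk)) {
            if (length(rows)) break else next
        }
        if (is.na(suppressWarnings(as.integer(tk[1]))))
            break                        # trailer (Lambda/K lines etc.)
        if (length(tk) < 22L)
            stop("format error at line ", i, ": expected position, ",
                 "residue and 20 scores, got ", length(tk), " fields")
        sc <- suppressWarnings(as.numeric(tk[3:22]))
        if (any(is.na(sc)))
            stop("format error at line ", i, ": non-numeric score")
        rows[[length(rows) + 1L]] <- sc
        letters1 <- c(letters1, tk[2])
    }
    if (!length(rows))
        stop("format error: PSSM contains no score rows")
    scores <- do.call(rbind, rows)
    colnames(scores) <- pssmAlphabet()
    rownames(scores) <- NULL
    new("PSSMProfile", sequence = paste(letters1, collapse = ""),
        scores = scores, nHits = NA_real_)
}

#' Write a PSSM in the PSI-BLAST ASCII layout
#'
#' @param profile A [PSSMProfile-class].
#' @param file Optional path; when omitted the lines are returned.
#' @return The text lines (invisibly when `file` is given).
#' @export
writePSSM <- function(profile, file = NULL) {
    stopifnot(is(profile, "PSSMProfile"))
    sc <- pssmScores(profile)
    letters1 <- strsplit(residueSequence(profile), "")[[1]]
    lines <- c(
        "",
        "Last position-specific scoring matrix computed",
        paste0("           ", paste(sprintf("%3s", pssmAlphabet()),
                                    collapse = " ")),
        vapply(seq_len(nrow(sc)), function(i)
            paste0(sprintf("%5d %s  ", i, letters1[i]),
                   paste(sprintf("%3d", as.integer(round(sc[i, ]))),
                         collapse = " ")),
            character(1)),
        "")
    if (is.null(file)) return(lines)
    writeLines(lines, file)
    invisible(lines)
}

#' Logistic normalization of a PSSM
#'
#' Replaces each raw log-odds score x with the logistic value
#' 1 / (1 + exp(-x)), squashing the matrix into the open interval
#' (0, 1).  A raw score of 0 (no information) maps to 0.5.
#'
#' @param profile A [PSSMProfile-class].
#' @return A [NormalizedProfile-class] of the same shape.
#' @export
#' @examples
#' profileValues(normalizeLogistic(pseudoProfile("AC")))[1, 1:4]
normalizeLogistic <- function(profile) {
    stopifnot(is(profile, "PSSMProfile"))
    v <- stats::plogis(pssmScores(profile))
    ## guard against saturation to exactly 0/1 for extreme scores
    eps <- .Machine$double.eps
    v <- pmin(pmax(v, eps), 1 - eps)
    new("NormalizedProfile", sequence = residueSequence(profile),
        values = v)
}

#' Substitution-matrix pseudo-profile
#'
#' A deterministic stand-in profile for use when no PSI-BLAST search is
#' possible: row i is the BLOSUM62 score row of residue i, in the
#' canonical 20-column order.  `X` residues get an all-zero row (which
#' normalizes to the uninformative value 0.5 everywhere).  This mirrors
#' what PSI-BLAST itself falls back to when a search finds no hits.
#'
#' @param sequence Protein sequence over the 20 amino acids plus `X`.
#' @return A [PSSMProfile-class] with `nHits = 0`.
#' @export
#' @examples
#' pssmScores(pseudoProfile("WX"))
pseudoProfile <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L,
              nchar(sequence) >= 1L)
    letters1 <- strsplit(sequence, "")[[1]]
    bad <- setdiff(letters1, c(pssmAlphabet(), "X"))
    if (length(bad))
        stop("sequence contains letters outside the amino-acid ",
             "alphabet: ", paste(unique(bad), collapse = ", "))
    blosum <- .blosum62()
    scores <- matrix(0, length(letters1), 20L,
                     dimnames = list(NULL, pssmAlphabet()))
    known <- letters1 != "X"
    scores[known, ] <- blosum[letters1[known], pssmAlphabet(),
                              drop = FALSE]
    new("PSSMProfile", sequence = sequence, scores = scores, nHits = 0)
}

.blosum62 <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            cache <<- e$BLOSUM62
        }
        cache
    }
})

.checkPaired <- function(p1, p2) {
    stopifnot(is(p1, "NormalizedProfile"), is(p2, "NormalizedProfile"))
    if (!identical(dim(profileValues(p1)), dim(profileValues(p2))))
        stop("dimension error: profiles have different shapes (L = ",
             nrow(profileValues(p1)), " vs ", nrow(profileValues(p2)), ")")
}

#' Normalized sum of squared distances between two profiles
#'
#' For two same-shape L x 20 normalized profiles P1 and P2,
#' `NSSD = (1 / (20 L)) * sum_ij (P1(i,j) - P2(i,j))^2`: the mean
#' squared entrywise difference.  Symmetric, zero exactly on identical
#' matrices, and at most 1 for entries in (0, 1).
#'
#' @param p1,p2 [NormalizedProfile-class] objects of equal length.
#' @return A non-negative number.
#' @seealso [nkl()], [meanPairwiseDistance()]
#' @export
nssd <- function(p1, p2) {
    .checkPaired(p1, p2)
    mean((profileValues(p1) - profileValues(p2))^2)
}

#' Symmetrized Kullback-Leibler profile divergence
#'
#' For two same-shape L x 20 normalized profiles with strictly positive
#' entries, `NKL = (1 / (2 * 20 L)) * sum_ij [P1 log(P1/P2) +
#' P2 log(P2/P1)]` with natural logarithms, applied entrywise to the
#' logistic-normalized values (no row renormalization).  Symmetric and
#' zero exactly on identical matrices.
#'
#' @param p1,p2 [NormalizedProfile-class] objects of equal length.
#' @return A non-negative number.
#' @seealso [nssd()]
#' @export
nkl <- function(p1, p2) {
    .checkPaired(p1, p2)
    a <- profileValues(p1); b <- profileValues(p2)
    if (any(a <= 0) || any(b <= 0))
        stop("domain error: NKL requires strictly positive entries")
    sum(a * log(a / b) + b * log(b / a)) / (2 * length(a))
}

#' Mean pairwise distance between two aligned profile collections
#'
#' Averages a profile distance over query-paired profile lists, e.g.
#' the profiles of one benchmark generated against two different
#' reference databases.
#'
#' @param profilesA,profilesB Lists of [NormalizedProfile-class],
#'   aligned by query: equal length, and the i-th elements must share
#'   their sequence.
#' @param metric `"nssd"` or `"nkl"`.
#' @return The arithmetic mean of the per-query distances.
#' @export
meanPairwiseDistance <- function(profilesA, profilesB,
                                 metric = c("nssd", "nkl")) {
    metric <- match.arg(metric)
    if (length(profilesA) != length(profilesB))
        stop("pairing error: profile lists differ in length")
    if (!length(profilesA)) stop("pairing error: empty profile lists")
    fn <- if (metric == "nssd") nssd else nkl
    d <- vapply(seq_along(profilesA), function(i) {
        if (!identical(residueSequence(profilesA[[i]]),
                       residueSequence(profilesB[[i]])))
            stop("pairing error: sequences differ at position ", i)
        fn(profilesA[[i]], profilesB[[i]])
    }, numeric(1))
    mean(d)
}
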