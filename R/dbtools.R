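## Reference-database tools: streaming FASTA record counting and
## seeded uniform subsampling (the "URkR" random database variants),
## plus the profile hit-count summary.

#' SamplePlan: how to subsample a sequence database
#'
#' @slot mode `"fraction"` (keep ceil(n * k / 100) records) or
#'   `"count"` (keep exactly `targetCount` records, e.g. to match the
#'   size of a similarity-reduced database).
#' @slot kPercent Percentage in (0, 100\] for fraction mode.
#' @slot targetCount Target record count for count mode.
#' @slot seed Integer seed; fully determines the sample.
#'
#' @seealso [samplePlan()], [sampleDatabase()]
#' @export
setClass("SamplePlan",
    representation(mode = "character", kPercent = "numeric",
                   targetCount = "integer", seed = "integer"))

setValidity("SamplePlan", function(object) {
    if (!object@mode %in% c("fraction", "count"))
        return("mode must be 'fraction' or 'count'")
    if (object@mode == "fraction" &&
        (is.na(object@kPercent) || object@kPercent <= 0 ||
         object@kPercent > 100))
        return("kPercent must lie in (0, 100]")
    if (object@mode == "count" &&
        (is.na(object@targetCount) || object@targetCount < 1L))
        return("targetCount must be >= 1")
    TRUE
})

#' Create a database sampling plan
#'
#' @param mode `"fraction"` or `"count"`.
#' @param kPercent Percentage of records to keep (fraction mode).
#' @param targetCount Number of records to keep (count mode).
#' @param seed Integer seed.
#' @return A [SamplePlan-class].
#' @export
#' @examples
#' samplePlan("fraction", kPercent = 1, seed = 42L)
samplePlan <- function(mode = c("fraction", "count"), kPercent = NA_real_,
                       targetCount = NA_integer_, seed = 1L) {
    mode <- match.arg(mode)
    new("SamplePlan", mode = mode, kPercent = as.numeric(kPercent),
        targetCount = as.integer(targetCount), seed = as.integer(seed))
}

#' Count records in a FASTA file (streaming)
#'
#' Counts `>` header lines while streaming the file in fixed-size line
#' chunks, so memory use is constant in the file size.  A record with
#' an empty header, or sequence data before the first header, is a
#' format error.
#'
#' @param dbPath Path to a FASTA file.
#' @return Integer record count (0 for an empty file).
#' @export
countSequences <- function(dbPath) {
    con <- file(dbPath, open = "r")
    on.exit(close(con))
    n <- 0L
    seenHeader <- FALSE
    repeat {
        lines <- readLines(con, n = 65536L)
        if (!length(lines)) break
        isHdr <- startsWith(lines, ">")
        if (any(isHdr & !nzchar(sub("^>\\s*", "", lines))))
            stop("format error: FASTA record with empty header")
        if (!seenHeader) {
            firstHdr <- match(TRUE, isHdr, nomatch = length(lines) + 1L)
            before <- lines[seq_len(firstHdr - 1L)]
            if (any(nzchar(trimws(before))))
                stop("format error: sequence data before first FASTA ",
                     "header")
        }
        if (any(isHdr)) seenHeader <- TRUE
        n <- n + sum(isHdr)
    }
    n
}

#' Sample size for a k-percent database fraction
#'
#' The number of records retained when sampling `k` percent of an
#' `n`-record database: `ceiling(n * k / 100)`.  The ceiling rule is
#' the unique simple rounding consistent with the published record
#' counts of the 10%, 5% and 1% uniform samples of the 50,371,270-
#' sequence reference database (5,037,127; 2,518,564; 503,713).
#'
#' @param n Database record count.
#' @param kPercent Percentage in (0, 100\].
#' @return Integer sample size; equals `n` at `kPercent = 100`.
#' @export
#' @examples
#' sampleSizeForFraction(50371270, 1)
sampleSizeForFraction <- function(n, kPercent) {
    stopifnot(n >= 1, kPercent > 0, kPercent <= 100)
    as.integer(ceiling(n * kPercent / 100))
}

## seeded uniform without-replacement index sample of 1..n, via
## reservoir sampling (Algorithm R); returned sorted so the sampled
## records keep their input order
.reservoirIndices <- function(n, k, seed) {
    stopifnot(k >= 1L, k <= n)
    .withSeed(as.integer(seed), function() {
        res <- seq_len(k)
        if (n > k) for (i in (k + 1L):n) {
            j <- sample.int(i, 1L)
            if (j <= k) res[j] <- i
        }
        sort(res)
    })
}

#' Uniformly subsample a FASTA database
#'
#' Draws a uniform without-replacement sample of records using
#' single-pass reservoir sampling (memory proportional to the sample,
#' not the database), then writes the sampled records byte-identically
#' and in their original order.  The seed in the plan fully determines
#' the sample, so identical calls produce identical files.  A manifest
#' JSON (source path and md5, seed, input and output counts) is written
#' beside the output.
#'
#' @param dbPath Input FASTA path.
#' @param plan A [SamplePlan-class].
#' @param outPath Output FASTA path.
#' @return `outPath`, invisibly; the output record count equals the
#'   planned size.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' synthFasta(20L, c(30L, 60L), seed = 1L, file = fa)
#' out <- tempfile(fileext = ".fasta")
#' sampleDatabase(fa, samplePlan("count", targetCount = 5L, seed = 9L), out)
#' countSequences(out)
sampleDatabase <- function(dbPath, plan, outPath) {
    stopifnot(is(plan, "SamplePlan"))
    n <- countSequences(dbPath)
    k <- switch(plan@mode,
        fraction = sampleSizeForFraction(n, plan@kPercent),
        count = plan@targetCount)
    if (k > n)
        stop("parameter error: target size ", k,
             " exceeds database size ", n)
    keep <- .reservoirIndices(n, k, plan@seed)

    con <- file(dbPath, open = "r")
    out <- file(outPath, open = "w")
    on.exit({ close(con); close(out) })
    idx <- 0L
    writing <- FALSE
    repeat {
        lines <- readLines(con, n = 65536L)
        if (!length(lines)) break
        for (l in lines) {            # record-boundary aware copy
            if (startsWith(l, ">")) {
                idx <- idx + 1L
                writing <- idx %in% keep
            }
            if (writing) writeLines(l, out)
        }
    }
    jsonlite::write_json(
        list(source = normalizePath(dbPath),
             md5 = unname(tools::md5sum(dbPath)),
             seed = plan@seed, mode = plan@mode,
             inputRecords = n, outputRecords = k),
        paste0(outPath, ".manifest.json"), auto_unbox = TRUE)
    invisible(outPath)
}

#' Mean PSI-BLAST hit count over a profile set
#'
#' @param profiles List of [PSSMProfile-class].  Profiles without a
#'   recorded hit count are excluded with a warning.
#' @param digits Rounding for the reported mean (default no rounding).
#' @return Arithmetic mean of the hit counts.
#' @export
hitCountReport <- function(profiles, digits = NULL) {
    hits <- vapply(profiles, nHits, numeric(1))
    if (anyNA(hits)) {
        warning(sum(is.na(hits)),
                " profile(s) missing a hit count; excluded")
        hits <- hits[!is.na(hits)]
    }
    if (!length(hits)) stop("no profiles with hit counts")
    m <- mean(hits)
    if (!is.null(digits)) m <- round(m, digits)
    m
}
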