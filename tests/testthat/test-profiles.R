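test_that("parsePSSM reads a hand-written ASCII matrix exactly", {
    txt <- c(
        "",
        "Last position-specific scoring matrix computed, weighted, ...",
        paste0("            ", paste(pssmAlphabet(), collapse = "   ")),
        paste("    1 M ", paste(1:20, collapse = "  "),
              paste(rep(0, 20), collapse = "  "), "0.30 0.09"),
        paste("    2 K ", paste(20:1, collapse = "  "),
              paste(rep(0, 20), collapse = "  "), "0.30 0.09"),
        paste("    3 V ", paste(rep(-2, 20), collapse = "  "),
              paste(rep(0, 20), collapse = "  "), "0.30 0.09"),
        "",
        "                      K         Lambda")
    p <- parsePSSM(txt)
    expect_identical(residueSequence(p), "MKV")
    expect_equal(unname(pssmScores(p)[1, ]), as.numeric(1:20))
    expect_equal(unname(pssmScores(p)[2, ]), as.numeric(20:1))
    expect_equal(unname(pssmScores(p)[3, ]), rep(-2, 20))
})

test_that("parsePSSM rejects malformed rows with a line number", {
    txt <- c(
        paste0("            ", paste(pssmAlphabet(), collapse = "   ")),
        paste("    1 M ", paste(1:19, collapse = "  ")))
    expect_error(parsePSSM(txt), "line 2")
    expect_error(parsePSSM("no matrix here"), "format error")
})

test_that("writePSSM/parsePSSM round-trip is lossless on integer scores", {
    set.seed(7)
    for (L in c(1L, 5L, 40L)) {
        seqv <- paste(sample(pssmAlphabet(), L, TRUE), collapse = "")
        sc <- matrix(sample(-12:12, L * 20L, TRUE), L, 20L,
                     dimnames = list(NULL, pssmAlphabet()))
        p <- new("PSSMProfile", sequence = seqv, scores = sc,
                 nHits = NA_real_)
        rt <- parsePSSM(writePSSM(p))
        expect_identical(residueSequence(rt), seqv)
        expect_equal(pssmScores(rt), sc)
    }
})

test_that("logistic normalization matches the closed form and is monotone", {
    sc <- matrix(0, 1L, 20L, dimnames = list(NULL, pssmAlphabet()))
    sc[1, 1:3] <- c(-2, 0, 3)
    sc[1, 4] <- 12
    v <- profileValues(normalizeLogistic(new("PSSMProfile",
        sequence = "A", scores = sc, nHits = NA_real_)))
    expect_equal(unname(v[1, 1]), 1 / (1 + exp(2)), tolerance = 1e-12)
    expect_equal(unname(v[1, 2]), 0.5, tolerance = 1e-12)
    expect_equal(unname(v[1, 3]), 1 / (1 + exp(-3)), tolerance = 1e-12)
    expect_gt(v[1, 4], 0.99); expect_lt(v[1, 4], 1.0)
    expect_true(all(v > 0 & v < 1))
    ## strictly monotone entrywise
    ord <- order(sc[1, ])
    expect_true(all(diff(v[1, ord][!duplicated(sc[1, ord])]) > 0))
})

test_that("pseudo-profiles reproduce the substitution-matrix rows", {
    p <- pseudoProfile("AAWX")
    sc <- pssmScores(p)
    expect_identical(sc[1, ], sc[2, ])              # determinism
    expect_identical(names(which.max(sc[3, ])), "W") # diagonal dominance
    expect_true(all(sc[4, ] == 0))                   # X row neutral
    ## independent lookup oracle straight from the published matrix
    data("BLOSUM62", package = "Biostrings", envir = environment())
    for (res in c("A", "W")) {
        i <- match(res, strsplit("AAWX", "")[[1]])
        expect_equal(unname(sc[i, ]),
                     unname(BLOSUM62[res, pssmAlphabet()]))
    }
    expect_error(pseudoProfile("AB2"), "alphabet")
})

test_that("nssd matches hand evaluation and the brute-force oracle", {
    base <- randNormProfile(1L, seed = 21)
    v1 <- profileValues(base); v2 <- v1
    v1[1, 1] <- 0.75; v2[1, 1] <- 0.25
    p1 <- new("NormalizedProfile", sequence = residueSequence(base),
              values = v1)
    p2 <- new("NormalizedProfile", sequence = residueSequence(base),
              values = v2)
    expect_equal(nssd(p1, p2), 0.5^2 / 20, tolerance = 1e-15)
    expect_equal(nssd(p1, p1), 0)
    expect_error(nssd(p1, randNormProfile(3L, seed = 1)), "dimension")
})

test_that("nkl matches hand evaluation of the symmetrized divergence", {
    base <- randNormProfile(1L, seed = 22)
    v1 <- profileValues(base); v2 <- v1
    v1[1, 1] <- 0.5; v2[1, 1] <- 0.25
    p1 <- new("NormalizedProfile", sequence = residueSequence(base),
              values = v1)
    p2 <- new("NormalizedProfile", sequence = residueSequence(base),
              values = v2)
    ## (1/40) * (0.5 log(0.5/0.25) + 0.25 log(0.25/0.5)) = log(2)/160
    expect_equal(nkl(p1, p2), log(2) / 160, tolerance = 1e-12)
    expect_equal(nkl(p1, p1), 0)
})

test_that("profile distances agree with double-loop oracles on random fixtures", {
    for (s in 1:10) {
        p1 <- randNormProfile(5L, seed = 100 + s)
        p2 <- randNormProfile(5L, seed = 200 + s,
                              sequence = residueSequence(p1))
        expect_equal(nssd(p1, p2), bruteNSSD(p1, p2), tolerance = 1e-12)
        expect_equal(nkl(p1, p2), bruteNKL(p1, p2), tolerance = 1e-12)
        expect_equal(nssd(p1, p2), nssd(p2, p1))
        expect_equal(nkl(p1, p2), nkl(p2, p1))
    }
})

test_that("mean pairwise distance averages per-query distances", {
    ps <- lapply(1:4, function(s) randNormProfile(6L, seed = 300 + s))
    qs <- lapply(seq_along(ps), function(i)
        new("NormalizedProfile", sequence = residueSequence(ps[[i]]),
            values = profileValues(randNormProfile(
                6L, seed = 400 + i,
                sequence = residueSequence(ps[[i]])))))
    expect_equal(meanPairwiseDistance(ps, ps, "nssd"), 0)
    manual <- mean(vapply(seq_along(ps), function(i)
        bruteNSSD(ps[[i]], qs[[i]]), numeric(1)))
    expect_equal(meanPairwiseDistance(ps, qs, "nssd"), manual,
                 tolerance = 1e-12)
    expect_error(meanPairwiseDistance(ps, qs[1:2]), "pairing")
    qs[[2]]@sequence <- paste(rev(strsplit(residueSequence(qs[[2]]),
                                           "")[[1]]), collapse = "")
    expect_error(meanPairwiseDistance(ps, qs, "nkl"), "pairing")
})

test_that("psiblast wrapper passes parameters through and round-trips", {
    cmd <- runPsiblast("AAA", "somedb", iterations = 4L,
                       evalue = 0.01, dryRun = TRUE)
    expect_match(cmd, "-num_iterations 4")
    expect_match(cmd, "-evalue 0.01")
    expect_match(cmd, "-inclusion_ethresh 0.01")
    expect_match(cmd, "-db somedb")
    expect_error(runPsiblast("AAA", "db", binary = "no-such-psiblast"),
                 "tool unavailable")

    ## live round trip on a tiny self-built database with known homologs
    set.seed(12)
    q <- paste(sample(pssmAlphabet(), 60, TRUE), collapse = "")
    mut <- vapply(1:5, function(i) {
        s <- strsplit(q, "")[[1]]
        pos <- sample(60, 6)
        s[pos] <- sample(pssmAlphabet(), 6, TRUE)
        paste(s, collapse = "")
    }, character(1))
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(rbind(paste0(">s", 0:5), c(q, mut))), fa)
    db <- withr::local_tempfile()
    system2("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", db),
            stdout = FALSE, stderr = FALSE)
    prof <- runPsiblast(q, db)
    expect_identical(residueSequence(prof), q)
    expect_identical(dim(pssmScores(prof)), c(60L, 20L))
    expect_gte(nHits(prof), 1)
})
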