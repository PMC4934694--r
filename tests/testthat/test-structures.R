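test_that("parseComplex reads a minimal complex and errors on degenerate input", {
    txt <- c(
        "REMARK   2 RESOLUTION.    2.50 ANGSTROMS.",
        "ATOM      1  CA  ALA A   1      10.000   0.000   0.000  1.00  0.00           C",
        "ATOM      2  CA  GLY A   2      13.800   0.000   0.000  1.00  0.00           C",
        "ATOM      3  P     A B   1      12.000   3.000   0.000  1.00  0.00           P",
        "END")
    cx <- parseComplex(txt, id = "mini")
    expect_identical(chainSequences(cx, "protein"), c(A = "AG"))
    expect_identical(unname(chainSequences(cx, "rna")), "a")
    expect_equal(resolution(cx), 2.5)

    ## not PDB at all
    expect_error(parseComplex("hello world"), "ATOM")
    ## RNA-only structure
    rnaOnly <- txt[c(1, 4, 5)]
    expect_error(parseComplex(rnaOnly), "no protein chains")
})

test_that("writePDB/parseComplex round-trips residue counts and coordinates", {
    cx <- synthComplex(12L, c(2L, 5L, 9L), seed = 3L)
    cx2 <- parseComplex(writePDB(cx), id = structureId(cx))
    expect_identical(chainSequences(cx2, "protein"),
                     chainSequences(cx, "protein"))
    a1 <- atomTable(cx); a2 <- atomTable(cx2)
    expect_identical(nrow(a1), nrow(a2))
    ord1 <- order(a1$chain, a1$resIndex, a1$atomName)
    ord2 <- order(a2$chain, a2$resIndex, a2$atomName)
    for (col in c("x", "y", "z"))
        expect_equal(a1[[col]][ord1], a2[[col]][ord2], tolerance = 1e-3)
    expect_equal(resolution(cx2), 2.0)
})

test_that("annotation obeys the distance cutoff at the boundary", {
    mk <- function(dy) {
        atoms <- data.frame(
            chain = c("A", "B"), resIndex = c(1L, 1L),
            code = c("A", "a"), kind = c("protein", "rna"),
            element = c("C", "P"), atomName = c("CA", "P"),
            x = 0, y = c(0, dy), z = 0)
        new("ComplexStructure", id = "d", atoms = atoms,
            resolution = 2.0)
    }
    expect_identical(interfaceLabels(annotateInterfaces(mk(4.9))[[1]]), 1L)
    expect_identical(interfaceLabels(annotateInterfaces(mk(5.0))[[1]]), 1L)
    expect_identical(interfaceLabels(annotateInterfaces(mk(5.1))[[1]]), 0L)
})

test_that("annotation recovers planted interfaces and matches brute force", {
    cx <- synthComplex(10L, c(3L, 7L), seed = 1L)
    ann <- annotateInterfaces(cx)[[1]]
    expect_identical(which(interfaceLabels(ann) == 1L), c(3L, 7L))
    expect_identical(interfaceLabels(ann),
                     bruteInterfaceLabels(cx, chainId(ann)))
})

test_that("annotation is invariant under atom permutation and monotone in cutoff", {
    cx <- synthComplex(15L, c(1L, 8L, 15L), seed = 4L)
    a <- atomTable(cx)
    set.seed(99)
    shuffled <- new("ComplexStructure", id = structureId(cx),
                    atoms = a[sample(nrow(a)), ],
                    resolution = resolution(cx))
    expect_identical(interfaceLabels(annotateInterfaces(cx)[[1]]),
                     interfaceLabels(annotateInterfaces(shuffled)[[1]]))
    counts <- vapply(c(1, 3, 5, 8, 12),
                     function(cut) sum(interfaceLabels(
                         annotateInterfaces(cx, cutoff = cut)[[1]])),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("a complex without RNA warns and labels everything 0", {
    cx <- synthComplex(8L, c(2L), seed = 1L)
    a <- atomTable(cx)
    noRNA <- new("ComplexStructure", id = "noRNA",
                 atoms = a[a$kind == "protein", ], resolution = 2.0)
    expect_warning(ann <- annotateInterfaces(noRNA), "no RNA")
    expect_identical(sum(interfaceLabels(ann[[1]])), 0L)
})

test_that("filterDataset applies each admission criterion in order", {
    good <- synthComplex(50L, c(3L, 10L, 20L, 30L), seed = 1L)
    tooShort <- synthComplex(39L, c(3L, 10L, 20L), seed = 2L)
    fewIfaces <- synthComplex(60L, c(5L, 25L), seed = 3L)
    lowRes <- synthComplex(50L, c(3L, 10L, 20L), seed = 4L)
    lowRes@resolution <- 3.5    # boundary: "less than 3.5" is strict
    noRes <- synthComplex(50L, c(3L, 10L, 20L), seed = 5L)
    noRes@resolution <- NA_real_
    good2 <- synthComplex(41L, c(1L, 2L, 3L, 4L), seed = 6L)

    res <- filterDataset(list(good, tooShort, fewIfaces, lowRes,
                              noRes, good2))
    expect_length(res$annotations, 2L)
    expect_identical(unname(res$rejections),
                     c(1L, 1L, 1L, 0L, 1L))   # unknown, res, len, rna, ifaces
    expect_identical(sum(res$rejections) + length(res$annotations), 6L)
})

test_that("greedy identity filter keeps a non-redundant subset", {
    A <- "MKTAYIAKQRELVDNGHWFS"
    B <- paste0("GESWFLVNDH", substr(A, 11, 20))  # 10/20 identical to A
    C <- paste0(strrep("PC", 10))                 # no letter shared with A
    pid <- RNAInterface:::.pairIdentity
    expect_equal(pid(A, A), 1)
    expect_equal(pid(A, B), 0.5)
    expect_equal(pid(A, C), 0)

    expect_identical(names(greedyIdentityFilter(c(a = A, b = A))), "a")
    expect_identical(names(greedyIdentityFilter(c(a = A, c = C))),
                     c("a", "c"))
    expect_identical(names(greedyIdentityFilter(c(a = A, b = B, c = C))),
                     c("a", "c"))
})

test_that("annotations round-trip through the label-file format", {
    anns <- list(mkAnnotation("ACDEF", c(0, 1, 0, 0, 1), "x1"),
                 mkAnnotation("WYK", c(1, 1, 0), "x2"))
    f <- withr::local_tempfile(fileext = ".txt")
    writeAnnotations(anns, f)
    back <- readAnnotations(f)
    expect_identical(names(back), c("x1", "x2"))
    expect_identical(interfaceLabels(back$x1), c(0L, 1L, 0L, 0L, 1L))
    expect_identical(residueSequence(back$x2), "WYK")

    ftsv <- withr::local_tempfile(fileext = ".tsv")
    writeAnnotations(anns, ftsv, format = "tsv")
    tab <- read.delim(ftsv)
    expect_identical(nrow(tab), 8L)
    expect_identical(sum(tab$label), 4L)
})
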