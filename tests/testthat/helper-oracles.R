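## Independent brute-force oracles used to freeze expected values.
## These deliberately share no code with the implementation paths they
## check.

## uniform random normalized profile away from the (0,1) boundary
randNormProfile <- function(L, seed, sequence = NULL) {
    set.seed(seed)
    if (is.null(sequence))
        sequence <- paste(sample(pssmAlphabet(), L, TRUE), collapse = "")
    v <- matrix(runif(L * 20L, 0.05, 0.95), L, 20L,
                dimnames = list(NULL, pssmAlphabet()))
    new("NormalizedProfile", sequence = sequence, values = v)
}

## double-loop profile distances
bruteNSSD <- function(p1, p2) {
    a <- profileValues(p1); b <- profileValues(p2)
    s <- 0
    for (i in seq_len(nrow(a))) for (j in 1:20)
        s <- s + (a[i, j] - b[i, j])^2
    unname(s / (20 * nrow(a)))
}

bruteNKL <- function(p1, p2) {
    a <- profileValues(p1); b <- profileValues(p2)
    s <- 0
    for (i in seq_len(nrow(a))) for (j in 1:20)
        s <- s + a[i, j] * log(a[i, j] / b[i, j]) +
                 b[i, j] * log(b[i, j] / a[i, j])
    unname(s / (2 * 20 * nrow(a)))
}

## AUC by exhaustive positive/negative pair enumeration, ties = 1/2
bruteAUC <- function(truth, scores) {
    pos <- scores[truth == 1]; neg <- scores[truth == 0]
    s <- 0
    for (p in pos) for (n in neg)
        s <- s + (p > n) + 0.5 * (p == n)
    s / (length(pos) * length(neg))
}

## confusion counts by an explicit loop
bruteConfusion <- function(truth, pred) {
    k <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (i in seq_along(truth)) {
        key <- if (truth[i] == 1 && pred[i] == 1) "TP"
               else if (truth[i] == 0 && pred[i] == 1) "FP"
               else if (truth[i] == 0 && pred[i] == 0) "TN"
               else "FN"
        k[key] <- k[key] + 1L
    }
    k
}

## all-pairs atom distance scan over a ComplexStructure
bruteInterfaceLabels <- function(complex, chain, cutoff = 5.0) {
    a <- atomTable(complex)
    prot <- a[a$kind == "protein" & a$chain == chain, , drop = FALSE]
    rna <- a[a$kind == "rna", , drop = FALSE]
    L <- max(prot$resIndex)
    labels <- integer(L)
    for (r in seq_len(L)) {
        pa <- prot[prot$resIndex == r, , drop = FALSE]
        hit <- FALSE
        for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(rna))) {
            d <- sqrt((pa$x[i] - rna$x[j])^2 + (pa$y[i] - rna$y[j])^2 +
                      (pa$z[i] - rna$z[j])^2)
            if (d <= cutoff) hit <- TRUE
        }
        labels[r] <- as.integer(hit)
    }
    labels
}

mkAnnotation <- function(sequence, labels, chain = "A")
    new("InterfaceAnnotation", chainId = chain, sequence = sequence,
        labels = as.integer(labels))
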