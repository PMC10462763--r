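# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, exhaustive enumeration) and never
# share code with the implementation paths they check.

# random DNA string
randSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                             collapse = "")

# random alignment as a named character vector
randAln <- function(n, L, labels = sprintf("t%02d", seq_len(n))) {
    setNames(vapply(seq_len(n), function(i) randSeq(L), character(1)),
             labels)
}

# brute-force motif scan: score every (position, strand) window by
# explicit per-base summation of the log2-odds matrix
bruteScan <- function(seq, motif, threshold) {
    lo <- motifLogOdds(motif)
    W <- ncol(lo)
    ch <- strsplit(toupper(seq), "")[[1]]
    rc <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    out <- list()
    for (s in 0:(length(ch) - W)) {
        win <- ch[(s + 1):(s + W)]
        sc <- 0
        for (j in seq_len(W))
            sc <- sc + if (win[j] %in% rownames(lo)) lo[win[j], j] else 0
        if (sc >= threshold)
            out[[length(out) + 1L]] <- data.frame(start = s, strand = "+",
                                                  score = sc)
        rwin <- rev(rc[win])
        sc <- 0
        for (j in seq_len(W))
            sc <- sc + if (rwin[j] %in% rownames(lo)) lo[rwin[j], j] else 0
        if (sc >= threshold)
            out[[length(out) + 1L]] <- data.frame(start = s, strand = "-",
                                                  score = sc)
    }
    if (!length(out))
        return(data.frame(start = integer(0), strand = character(0),
                          score = numeric(0)))
    d <- do.call(rbind, out)
    d[order(d$start, d$strand != "+"), , drop = FALSE]
}

# one-sided hypergeometric tail p for a 2x2 table (a of n1 vs b of n2):
# probability of >= a successes in the primary margin
bruteFisherP <- function(a, n1, b, n2) {
    K <- a + b              # total "hit" sequences
    N <- n1 + n2
    num <- 0; den <- 0
    for (x in max(0, K - n2):min(K, n1)) {
        term <- choose(n1, x) * choose(n2, K - x)
        den <- den + term
        if (x >= a) num <- num + term
    }
    num / den
}

# brute-force Fitch: minimum changes over all internal-state labelings
# of an unrooted tree given as a Newick string (no missing data)
bruteFitchLength <- function(aln, newick) {
    tr <- ape::unroot(ape::read.tree(text = newick))
    n <- length(tr$tip.label)
    edges <- tr$edge
    nInternal <- tr$Nnode
    states <- c("A", "C", "G", "T")
    chm <- do.call(rbind, strsplit(toupper(aln[tr$tip.label]), ""))
    combos <- as.matrix(expand.grid(rep(list(states), nInternal),
                                    stringsAsFactors = FALSE))
    total <- 0
    for (site in seq_len(ncol(chm))) {
        best <- Inf
        for (r in seq_len(nrow(combos))) {
            lab <- c(chm[, site], combos[r, ])
            ch <- sum(lab[edges[, 1]] != lab[edges[, 2]])
            if (ch < best) best <- ch
        }
        total <- total + best
    }
    total
}

# adjusted Rand index between two labelings (comparison helper)
adjRandIndex <- function(x, y) {
    tab <- table(x, y)
    a <- sum(choose(tab, 2))
    b <- sum(choose(rowSums(tab), 2))
    cc <- sum(choose(colSums(tab), 2))
    n <- sum(tab)
    expected <- b * cc / choose(n, 2)
    maxi <- (b + cc) / 2
    if (maxi == expected) return(1)
    (a - expected) / (maxi - expected)
}

# small default config for fast end-to-end runs
smallSimConfig <- function(seed = 1, ...) {
    args <- list(seed = seed, upstream = 200, downstream = 100,
                 motifOffset = -80, genesPerDataset = 40, nPlanted = 8,
                 scGenes = 100, scCellsPerSample = 80, scSamples = 8)
    over <- list(...)
    args[names(over)] <- over
    do.call(simConfig, args)
}
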