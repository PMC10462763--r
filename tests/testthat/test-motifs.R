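# Motif parsing, promoter windows, scanning, differential enrichment.

test_that("JASPAR parsing preserves counts and round-trips", {
    txt <- c(">M1 toy",
             "A [ 10  0  0  0 ]",
             "C [  0 10  0  0 ]",
             "G [  0  0 10  0 ]",
             "T [  0  0  0 10 ]")
    m <- readJaspar(text = txt)[[1]]
    expect_equal(motifConsensus(m), "ACGT")
    expect_equal(unname(m@counts["A", ]), c(10, 0, 0, 0))
    # log-odds of the consensus base: log2((10.5/12)/0.25)
    expect_equal(unname(motifLogOdds(m)["A", 1]), log2((10.5 / 12) / 0.25))
    tf <- tempfile()
    writeJaspar(m, tf)
    m2 <- readJaspar(tf)[[1]]
    expect_equal(m2@counts, m@counts)
    expect_equal(motifConsensus(m2), "ACGT")
})

test_that("JASPAR parsing rejects malformed records with context", {
    ragged <- c(">M1 x", "A [ 1 2 ]", "C [ 1 2 3 ]", "G [ 1 2 ]",
                "T [ 1 2 ]")
    expect_error(readJaspar(text = ragged), "ragged")
    neg <- c(">M1 x", "A [ 1 -2 ]", "C [ 1 2 ]", "G [ 1 2 ]", "T [ 1 2 ]")
    expect_error(readJaspar(text = neg), "negative")
    lab <- c(">M1 x", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]", "X [ 1 2 ]")
    expect_error(readJaspar(text = lab), "labels|unparseable")
})

test_that("promoter window coordinates follow the TSS/strand convention", {
    ctg <- setNames(paste(rep("ACGT", 5000), collapse = ""), "chr1")
    wp <- promoterWindow("g", "chr1", 10000, "+", ctg, 2000, 1000)
    expect_equal(c(wp$start, wp$end), c(8000, 11000))
    wm <- promoterWindow("g", "chr1", 10000, "-", ctg, 2000, 1000)
    expect_equal(c(wm$start, wm$end), c(9001, 12001))
    expect_false(wp$clipped)
    # clipping is flagged
    expect_true(promoterWindow("g", "chr1", 100, "+", ctg, 2000, 1000)$clipped)
    expect_error(promoterWindow("g", "chr1", 100, "+", ctg, -1, 10),
                 "non-negative")
})

test_that("opposite-strand windows at mirrored TSSs are reverse complements", {
    set.seed(71)
    ctg <- setNames(randSeq(3000), "c")
    rcc <- setNames(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(ctg[[1]]))), "c")
    t1 <- 1500
    t2 <- 3000 - 1 - t1   # mirrored TSS on the reverse-complement contig
    a <- promoterWindow("g", "c", t1, "+", ctg, 300, 150)
    b <- promoterWindow("g", "c", t2, "-", rcc, 300, 150)
    expect_equal(a$seq, b$seq)
})

test_that("scanning the consensus at the maximum score yields one + hit", {
    m <- bundledMotifs()$AP1
    h <- scanMotif(motifConsensus(m), m, threshold = motifMaxScore(m))
    expect_equal(nrow(h), 1L)
    expect_equal(h$start, 0L)
    expect_equal(h$strand, "+")
    # above the maximum nothing can match
    set.seed(5)
    h2 <- scanMotif(randSeq(300), m, threshold = motifMaxScore(m) + 1e-6)
    expect_equal(nrow(h2), 0L)
})

test_that("scan agrees with the brute-force scorer on random sequences", {
    m <- bundledMotifs()$AP1
    set.seed(42)
    for (i in 1:50) {
        s <- randSeq(200)
        thr <- 0.55 * motifMaxScore(m)
        mine <- scanMotif(s, m, threshold = thr)
        ref <- bruteScan(s, m, thr)
        expect_equal(nrow(mine), nrow(ref))
        if (nrow(ref)) {
            expect_equal(mine$start, ref$start)
            expect_equal(mine$strand, ref$strand)
            expect_equal(mine$score, ref$score, tolerance = 1e-12)
        }
    }
})

test_that("scan hits map correctly onto the reverse complement", {
    m <- bundledMotifs()$SPI1
    set.seed(9)
    for (i in 1:10) {
        s <- randSeq(150)
        rc <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(s)))
        thr <- 0.5 * motifMaxScore(m)
        h1 <- scanMotif(s, m, threshold = thr)
        h2 <- scanMotif(rc, m, threshold = thr)
        expect_equal(nrow(h1), nrow(h2))
        if (nrow(h1)) {
            L <- nchar(s); W <- motifWidth(m)
            mapped <- sort(L - W - h1$start)
            expect_equal(sort(h2$start), mapped)
        }
    }
})

test_that("raising the threshold never adds hits", {
    m <- bundledMotifs()$SP1
    set.seed(3)
    s <- randSeq(400)
    lo <- scanMotif(s, m, threshold = 0.4 * motifMaxScore(m))
    hi <- scanMotif(s, m, threshold = 0.7 * motifMaxScore(m))
    expect_true(nrow(hi) <= nrow(lo))
    key <- function(h) paste(h$start, h$strand)
    expect_true(all(key(hi) %in% key(lo)))
})

test_that("the 3-vs-12 clade table gives the exact hypergeometric p", {
    m <- bundledMotifs()
    cons <- motifConsensus(m$AP1)
    set.seed(11)
    # AT-rich backgrounds cannot contain spurious AP1/SPI1/SP1 hits at
    # the default threshold
    bg <- function() paste(sample(c("A", "T"), 60, TRUE), collapse = "")
    primary <- vapply(1:3, function(i) {
        s <- bg(); paste0(substr(s, 1, 20), cons,
                          substr(s, 21 + nchar(cons), 60))
    }, character(1))
    control <- vapply(1:12, function(i) bg(), character(1))
    en <- motifEnrichment(primary, control, m["AP1"])
    expect_equal(en$a, 3L)
    expect_equal(en$b, 0L)
    expect_equal(en$p, 1 / 455, tolerance = 1e-12)
    expect_equal(en$p, bruteFisherP(3, 3, 0, 12), tolerance = 1e-12)
})

test_that("equal presence proportions give ratio 1 and a null p", {
    m <- bundledMotifs()["AP1"]
    cons <- motifConsensus(m$AP1)
    set.seed(12)
    withSite <- function() paste0(paste(sample(c("A", "T"), 20, TRUE),
                                        collapse = ""), cons)
    without <- function() paste(sample(c("A", "T"), 31, TRUE), collapse = "")
    primary <- c(withSite(), withSite(), without(), without())
    control <- c(withSite(), withSite(), without(), without())
    en <- motifEnrichment(primary, control, m)
    expect_equal(en$ratio, 1)
    expect_gte(en$p, 0.5)
})

test_that("enrichment p matches brute hypergeometric tails over random tables", {
    m <- bundledMotifs()["AP1"]
    cons <- motifConsensus(m$AP1)
    set.seed(77)
    for (i in 1:25) {
        n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
        a <- sample(0:n1, 1); b <- sample(0:n2, 1)
        mk <- function(hit) if (hit)
            paste0(paste(sample(c("A", "T"), 15, TRUE), collapse = ""), cons)
        else paste(sample(c("A", "T"), 26, TRUE), collapse = "")
        primary <- vapply(seq_len(n1), function(j) mk(j <= a), character(1))
        control <- vapply(seq_len(n2), function(j) mk(j <= b), character(1))
        en <- motifEnrichment(primary, control, m)
        expect_equal(en$a, a)
        expect_equal(en$b, b)
        expect_equal(en$p, bruteFisherP(a, n1, b, n2), tolerance = 1e-9)
    }
})

test_that("motifs wider than the shortest sequence warn, not fail", {
    m <- bundledMotifs()
    en <- motifEnrichment(c("ACGT"), c("TTTT"), m)
    expect_true(all(nzchar(en$note)))
    expect_true(all(is.na(en$p)))
})
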