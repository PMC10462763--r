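# Fitch counting, TBR search, bootstrap support, CI/RI.

test_that("Fitch length matches hand-worked 4-taxon cases", {
    expect_equal(fitchLength(c(s1 = "A", s2 = "A", s3 = "C", s4 = "C"),
                             "((s1,s2),(s3,s4));"), 1L)
    expect_equal(fitchLength(c(s1 = "A", s2 = "C", s3 = "A", s4 = "C"),
                             "((s1,s2),(s3,s4));"), 2L)
    # identical sequences need no changes
    expect_equal(fitchLength(c(a = "ACGT", b = "ACGT", c = "ACGT",
                               d = "ACGT"), "((a,b),(c,d));"), 0L)
})

test_that("Fitch equals the brute-force minimum over internal labelings", {
    set.seed(21)
    for (i in 1:12) {
        aln <- randAln(6, 8)
        nwk <- ape::write.tree(ape::rtree(6, tip.label = names(aln)))
        expect_equal(fitchLength(aln, nwk),
                     bruteFitchLength(aln, nwk))
    }
})

test_that("Fitch is invariant to rooting, leaf order and site order", {
    set.seed(22)
    aln <- randAln(8, 30)
    tr <- ape::rtree(8, tip.label = names(aln))
    L0 <- fitchLength(aln, tr)
    expect_equal(fitchLength(aln[sample(names(aln))], tr), L0)
    expect_equal(fitchLength(aln, ape::root(tr, names(aln)[5],
                                            resolve.root = TRUE)), L0)
    perm <- sample(30)
    alnP <- vapply(aln, function(s)
        paste(strsplit(s, "")[[1]][perm], collapse = ""), character(1))
    expect_equal(fitchLength(alnP, tr), L0)
})

test_that("gaps and N act as missing data", {
    aln <- c(a = "A-", b = "AN", c = "C-", d = "CN")
    # second site is all-missing, first site needs one change
    expect_equal(fitchLength(aln, "((a,b),(c,d));"), 1L)
})

test_that("TBR search finds the exhaustive optimum on small instances", {
    suppressPackageStartupMessages(requireNamespace("phangorn"))
    set.seed(31)
    for (i in 1:6) {
        n <- 6
        aln <- randAln(n, 40)
        pd <- phangorn::phyDat(do.call(rbind, strsplit(aln, "")))
        allt <- phangorn::allTrees(n, rooted = FALSE,
                                   tip.label = names(aln))
        exh <- min(vapply(allt,
                          function(tt) phangorn::parsimony(tt, pd),
                          numeric(1)))
        pt <- tbrSearch(aln, restarts = 4, seed = i)
        expect_equal(treeScore(pt), as.integer(exh))
    }
})

test_that("TBR result beats or ties arbitrary user topologies", {
    set.seed(32)
    aln <- randAln(8, 60)
    pt <- tbrSearch(aln, restarts = 5, seed = 1)
    for (i in 1:10) {
        rt <- ape::rtree(8, tip.label = names(aln))
        expect_lte(treeScore(pt), fitchLength(aln, rt))
    }
})

test_that("duplicating a taxon never increases tree length", {
    set.seed(33)
    for (i in 1:5) {
        aln <- randAln(6, 40)
        dup <- c(aln, dup1 = unname(aln[3]))
        l1 <- treeScore(tbrSearch(aln, restarts = 4, seed = i))
        l2 <- treeScore(tbrSearch(dup, restarts = 4, seed = i))
        expect_lte(l2, l1)
    }
})

test_that("search is deterministic given the seed and taxon-order invariant", {
    set.seed(34)
    aln <- randAln(7, 50)
    a <- tbrSearch(aln, restarts = 3, seed = 9)
    b <- tbrSearch(aln, restarts = 3, seed = 9)
    expect_equal(ape::write.tree(treeTopology(a)),
                 ape::write.tree(treeTopology(b)))
    sh <- tbrSearch(aln[sample(names(aln))], restarts = 3, seed = 9)
    expect_equal(treeScore(sh), treeScore(a))
    expect_equal(phangorn::RF.dist(treeTopology(sh), treeTopology(a)), 0)
})

test_that("CI and RI match the worked 4-taxon, 2-site example", {
    aln <- c(s1 = "AA", s2 = "AC", s3 = "CA", s4 = "CC")
    r <- ciRi(aln, "((s1,s2),(s3,s4));")
    expect_equal(r$length, 3L)
    expect_equal(r$ci, 2 / 3)
    expect_equal(r$ri, 0.5)
    # homoplasy-free alignment: every site fits the tree perfectly
    hf <- c(s1 = "AAG", s2 = "AAG", s3 = "CAG", s4 = "CTG")
    expect_equal(ciRi(hf, "((s1,s2),(s3,s4));")$ci, 1)
})

test_that("CI * L = M identically on random instances", {
    set.seed(41)
    for (i in 1:20) {
        aln <- randAln(6, 25)
        tr <- ape::rtree(6, tip.label = names(aln))
        r <- ciRi(aln, tr)
        expect_equal(r$ci * r$length, r$M, tolerance = 1e-12)
        expect_gte(r$ci, 0); expect_lte(r$ci, 1)
        if (!is.na(r$ri)) { expect_gte(r$ri, 0); expect_lte(r$ri, 1) }
        # observed length can never undercut the conceivable minimum
        expect_gte(r$length, r$M)
    }
})

test_that("a 50-site clade split earns 100% bootstrap support", {
    set.seed(51)
    base <- sample(c("A", "C", "G", "T"), 60, TRUE)
    alt <- base
    alt[1:50] <- ifelse(base[1:50] == "A", "C", "A")
    aln <- setNames(c(rep(paste(base, collapse = ""), 3),
                      rep(paste(alt, collapse = ""), 3)),
                    c(paste0("x", 1:3), paste0("y", 1:3)))
    bt <- bootstrapSupport(aln, reps = 100, seed = 1, restarts = 3)
    supp <- treeSupport(bt)
    expect_true(all(supp >= 0 & supp <= 100))
    # the x/y bipartition is present in every replicate
    expect_true(100 %in% supp)
    phy <- treeTopology(bt)
    grp <- which(vapply(ape::prop.part(phy), length, integer(1)) > 0)
    expect_true(ape::is.monophyletic(phy, paste0("x", 1:3)) ||
                ape::is.monophyletic(phy, paste0("y", 1:3)))
})

test_that("a single bootstrap replicate yields only 0 or 100", {
    set.seed(52)
    aln <- randAln(6, 30)
    bt <- bootstrapSupport(aln, reps = 1, seed = 2, restarts = 2)
    expect_true(all(treeSupport(bt) %in% c(0, 100)))
})

test_that("equal-sequence alignments earn no confident resolved edges", {
    aln <- setNames(rep(paste(rep("ACGT", 10), collapse = ""), 6),
                    paste0("t", 1:6))
    for (s in 1:3) {
        bt <- bootstrapSupport(aln, reps = 20, seed = s, restarts = 1)
        # ignore the basal node (trivial bipartition)
        expect_true(all(treeSupport(bt)[-1] <= 70))
    }
})

test_that("the planted Muroidea-like clade is recovered from promoters", {
    rec <- 0
    for (s in 1:10) {
        pr <- simulatePromoters(simConfig(seed = s))
        pt <- tbrSearch(pr$alignment, restarts = 1, seed = s)
        if (ape::is.monophyletic(treeTopology(pt),
                                 c("mouse", "rat", "chinese_hamster")))
            rec <- rec + 1
    }
    expect_gte(rec, 9)
})

test_that("input validation raises labelled errors", {
    aln <- randAln(4, 10)
    expect_error(tbrSearch(aln, restarts = 0), "restarts")
    expect_error(fitchLength(aln, "((t01,t02),(t03,badname));"),
                 "leaf set")
    expect_error(tbrSearch(randAln(3, 10)), "at least 4")
})
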