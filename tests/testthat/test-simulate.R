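# Synthetic-data generators: determinism, limiting cases, truth
# recoverability.

test_that("promoter generation is byte-deterministic under a fixed seed", {
    a <- simulatePromoters(simConfig(seed = 5))
    b <- simulatePromoters(simConfig(seed = 5))
    f1 <- tempfile(); f2 <- tempfile()
    writeFasta(a$sequences, f1); writeFasta(b$sequences, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(a$truth, b$truth)
    c <- simulatePromoters(simConfig(seed = 6))
    expect_false(identical(a$sequences, c$sequences))
})

test_that("zero substitution rate freezes every non-clade leaf", {
    pr <- simulatePromoters(simConfig(seed = 2, substitutionRateScale = 0))
    out <- pr$sequences[!pr$truth$inClade]
    expect_true(all(out == out[[1]]))
    # clade leaves equal the frozen sequence outside the planted window
    s0 <- out[[1]]
    tr <- pr$truth[pr$truth$inClade, ][1, ]
    cl <- pr$sequences[[tr$leaf]]
    expect_identical(substr(cl, 1, tr$motifStart),
                     substr(s0, 1, tr$motifStart))
    expect_identical(substring(cl, tr$motifEnd + 1),
                     substring(s0, tr$motifEnd + 1))
    expect_identical(substring(cl, tr$motifStart + 1, tr$motifEnd),
                     tr$instance)
})

test_that("the planted motif is found in all clade leaves and few others", {
    m <- bundledMotifs()$AP1
    cladeHits <- 0; cladeTotal <- 0; outHits <- 0; outTotal <- 0
    for (s in 1:20) {
        pr <- simulatePromoters(simConfig(seed = s))
        for (i in seq_len(nrow(pr$truth))) {
            h <- scanMotif(pr$sequences[[i]], m,
                           threshold = 0.8 * motifMaxScore(m))
            hStrict <- scanMotif(pr$sequences[[i]], m,
                                 threshold = 0.95 * motifMaxScore(m))
            if (pr$truth$inClade[i]) {
                cladeTotal <- cladeTotal + 1
                if (nrow(h) > 0) cladeHits <- cladeHits + 1
            } else {
                outTotal <- outTotal + 1
                if (nrow(hStrict) > 0) outHits <- outHits + 1
            }
        }
    }
    expect_equal(cladeHits, cladeTotal)          # 100% of clade leaves
    expect_lte(outHits / outTotal, 0.05)         # <= 5% of the rest
})

test_that("planting validation raises labelled errors", {
    expect_error(simulatePromoters(
        simConfig(plantedClade = c("mouse", "unicorn"))), "absent")
    expect_error(simulatePromoters(
        simConfig(motifOffset = 600)), "overrun")
    expect_error(simConfig(samplesPerGroup = 2), "samplesPerGroup")
    expect_error(simConfig(nbDispersion = 0), "positive")
    expect_error(simConfig(cellTypeProportions = c(a = 0.6, b = 0.3)),
                 "sum to 1")
    expect_error(simConfig(sigma = NaN), "finite")
})

test_that("noise-free expression reproduces the planted shift exactly", {
    w <- simulateExpressionDatasets(
        simConfig(seed = 3, genesPerDataset = 20, nPlanted = 5,
                  sigma = 0, tau = 0, thetaMean = 2, countsFraction = 0))
    for (d in seq_along(w$datasets)) {
        ds <- w$datasets[[d]]
        stim <- ds@condition == "stimulated"
        diff <- rowMeans(ds@exprs[, stim]) - rowMeans(ds@exprs[, !stim])
        expect_equal(unname(diff), unname(w$truth$delta[, d]),
                     tolerance = 1e-10)
    }
})

test_that("group means ignore sample column order", {
    w <- simulateExpressionDatasets(simConfig(seed = 4, genesPerDataset = 15))
    ds <- w$datasets[[3]]
    o <- sample(ncol(ds@exprs))
    perm <- DatasetExpression(ds@id, ds@exprs[, o], ds@condition[o],
                              ds@platform)
    e1 <- perDatasetDE(ds); e2 <- perDatasetDE(perm)
    expect_equal(e1$logFC, e2$logFC, tolerance = 1e-12)
})

test_that("single-cell counts conserve totals and respect labels", {
    sc <- simulateScCounts(smallSimConfig(seed = 7))
    expect_equal(sum(sc$counts),
                 sum(Matrix::colSums(sc$counts)))
    expect_equal(ncol(sc$counts), nrow(sc$cells))
    expect_true(all(sc$cells$subcluster[sc$cells$cellType != "microglia"]
                    == "none"))
    expect_true(all(sc$cells$subcluster[sc$cells$cellType == "microglia"]
                    %in% c("activated", "homeostatic")))
})

test_that("the Poisson limit has unit variance-to-mean ratio", {
    ratios <- numeric(0)
    for (s in 1:10) {
        sc <- simulateScCounts(
            smallSimConfig(seed = s, nbDispersion = Inf,
                           scCellsPerSample = 120, scLibrarySd = 0))
        ct <- sc$cells$cellType
        # background genes within one cell type are i.i.d. Poisson
        bg <- setdiff(rownames(sc$counts),
                      unlist(sc$truth[c("activation", "homeostatic",
                                        "specific", "panCellular")]))
        m <- as.matrix(sc$counts[bg, ct == "neuron"])
        keep <- rowMeans(m) > 0.5
        ratios <- c(ratios,
                    mean(apply(m[keep, ], 1, var) / rowMeans(m[keep, ])))
    }
    expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("activation genes are higher in the activated subcluster", {
    up <- 0
    for (s in 1:20) {
        sc <- simulateScCounts(smallSimConfig(seed = s))
        act <- sc$cells$subcluster == "activated"
        hom <- sc$cells$subcluster == "homeostatic"
        mAct <- Matrix::rowMeans(sc$counts[sc$truth$activation, act])
        mHom <- Matrix::rowMeans(sc$counts[sc$truth$activation, hom])
        if (all(mAct > mHom)) up <- up + 1
    }
    expect_gte(up, 19)
})

test_that("annotation truth equals realised interval overlap", {
    ann <- simulateAnnotationIntervals(simConfig(seed = 8), nGenes = 150)
    ap1 <- ann$intervals[ann$intervals$tf %in% AP1_FAMILY, ]
    for (i in which(ann$truth$occupied)) {
        g <- ann$genes[i, ]
        ws <- if (g$strand == "+") g$tss - 2000 else g$tss - 1000 + 1
        we <- if (g$strand == "+") g$tss + 1000 else g$tss + 2000 + 1
        expect_true(any(pmin(ap1$end, we) - pmax(ap1$start, ws) >= 1))
    }
    # BED bytes are deterministic
    f1 <- tempfile(); f2 <- tempfile()
    writeBed(ann$intervals, f1)
    writeBed(simulateAnnotationIntervals(simConfig(seed = 8),
                                         nGenes = 150)$intervals, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("stream seeds are independent and reproducible", {
    expect_equal(substreamSeed(42, "promoters"),
                 substreamSeed(42, "promoters"))
    expect_false(substreamSeed(42, "promoters") ==
                 substreamSeed(42, "expression"))
    expect_false(substreamSeed(42, "promoters") ==
                 substreamSeed(43, "promoters"))
    expect_lt(substreamSeed(.Machine$integer.max, "x"), 2^31)
})
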