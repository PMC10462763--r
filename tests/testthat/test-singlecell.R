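# AUCell-style scoring, subcluster labelling, pseudobulk, DE,
# cell-type specificity.

test_that("AUCell score hits 1 for a top-k set and 0 for an absent set", {
    counts <- matrix(c(100:1), nrow = 100,
                     dimnames = list(sprintf("g%03d", 1:100), "c1"))
    top5 <- sprintf("g%03d", 1:5)
    s <- aucellScore(counts, top5, topFraction = 0.1)
    expect_equal(s$score, 1)
    bottom <- sprintf("g%03d", 96:100)
    s0 <- aucellScore(counts, bottom, topFraction = 0.05)
    expect_equal(s0$score, 0)
    expect_error(aucellScore(counts, c("nope1", "nope2")), "no overlap")
})

test_that("AUCell equals brute-force recovery-curve integration", {
    set.seed(81)
    G <- 60
    counts <- matrix(rpois(G * 20, 5), nrow = G,
                     dimnames = list(sprintf("g%03d", 1:G),
                                     sprintf("c%02d", 1:20)))
    for (rep in 1:5) {
        gs <- sample(rownames(counts), 8)
        sc <- aucellScore(counts, gs, topFraction = 0.2, seed = 7)
        maxRank <- ceiling(0.2 * G)
        tie <- withr::with_seed(substreamSeed(7, "aucell-ties"),
                                sample.int(G))
        for (j in sample(20, 4)) {
            ord <- order(-counts[, j], tie)[1:maxRank]
            hits <- cumsum(rownames(counts)[ord] %in% gs)
            ref <- sum(hits) / sum(pmin(1:maxRank, length(gs)))
            expect_equal(sc$score[j], ref)
        }
    }
})

test_that("AUCell is invariant to monotone count transformations", {
    set.seed(82)
    counts <- matrix(rpois(50 * 10, 4), nrow = 50,
                     dimnames = list(sprintf("g%03d", 1:50),
                                     sprintf("c%02d", 1:10)))
    gs <- sample(rownames(counts), 6)
    a <- aucellScore(counts, gs, topFraction = 0.2, seed = 3)
    b <- aucellScore(counts^2 + 1, gs, topFraction = 0.2, seed = 3)
    expect_equal(a$score, b$score)
})

test_that("subclusters are labelled by their dominant signature", {
    sc <- simulateScCounts(smallSimConfig(seed = 4))
    mg <- sc$cells$cellType == "microglia"
    cm <- sc$counts[, mg]
    sets <- list(activation = sc$truth$activation,
                 homeostatic = sc$truth$homeostatic,
                 background = rownames(cm)[60:70])
    scores <- do.call(rbind, lapply(names(sets), function(nm)
        aucellScore(cm, sets[[nm]], topFraction = 0.2, setName = nm)))
    sub <- setNames(sc$cells$subcluster[mg], sc$cells$cell[mg])
    lab <- labelSubclusters(scores, sub)
    expect_equal(lab$label[lab$subcluster == "activated"], "activation")
    expect_equal(lab$label[lab$subcluster == "homeostatic"], "homeostatic")
    # label assignment ignores subcluster order
    lab2 <- labelSubclusters(scores, sub[sample(length(sub))])
    expect_equal(lab, lab2)
})

test_that("indistinguishable subclusters come back ambiguous", {
    cells <- sprintf("c%02d", 1:40)
    scores <- rbind(
        data.frame(cell = cells, geneSet = "setA", score = 0.5),
        data.frame(cell = cells, geneSet = "setB", score = 0.5))
    sub <- setNames(rep(c("s1", "s2"), each = 20), cells)
    lab <- labelSubclusters(scores, sub)
    expect_true(all(lab$label == "ambiguous"))
})

test_that("pseudobulk sums exactly and conserves the grand total", {
    set.seed(91)
    G <- 50
    counts <- matrix(rpois(G * 200, 3), nrow = G,
                     dimnames = list(sprintf("g%03d", 1:G),
                                     sprintf("c%03d", 1:200)))
    cells <- data.frame(
        cell = colnames(counts),
        sample = sample(paste0("s", 1:4), 200, TRUE),
        cellType = sample(c("mg", "ast"), 200, TRUE))
    pb <- pseudobulk(counts, cells, minCells = 0)
    m <- SummarizedExperiment::assay(pb)
    expect_equal(sum(m), sum(counts))
    # brute-force per-gene loop
    cd <- as.data.frame(SummarizedExperiment::colData(pb))
    for (j in sample(ncol(m), 4)) {
        sel <- cells$sample == cd$sample[j] & cells$cellType == cd$cellType[j]
        for (g in sample(G, 5))
            expect_equal(m[g, j], sum(counts[g, sel]))
    }
    # invariance to cell order
    o <- sample(200)
    pb2 <- pseudobulk(counts[, o], cells[o, ], minCells = 0)
    expect_equal(SummarizedExperiment::assay(pb2)[, colnames(m)], m)
})

test_that("a single cell per column passes through unchanged; the floor drops", {
    counts <- matrix(1:8, nrow = 2,
                     dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
    cells <- data.frame(cell = paste0("c", 1:4),
                        sample = paste0("s", 1:4),
                        cellType = "mg")
    pb <- pseudobulk(counts, cells, minCells = 1)
    expect_equal(unname(SummarizedExperiment::assay(pb)), unname(counts))
    pb2 <- pseudobulk(counts, cells, minCells = 2)
    expect_equal(ncol(pb2), 0L)
    expect_equal(length(S4Vectors::metadata(pb2)$dropped), 4L)
})

test_that("swapping contrast levels negates every logFC", {
    sc <- simulateScCounts(smallSimConfig(seed = 6))
    mg <- sc$cells$cellType == "microglia"
    pb <- pseudobulk(sc$counts[, mg], sc$cells[mg, ],
                     by = c("sample", "subcluster"), minCells = 3)
    a <- pseudobulkDE(pb, "subcluster", ref = "homeostatic")
    b <- pseudobulkDE(pb, "subcluster", ref = "activated")
    expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("log-CPM is invariant to library scaling", {
    set.seed(92)
    counts <- matrix(rpois(40 * 6, 20), nrow = 40)
    doubled <- counts
    doubled[, 3] <- counts[, 3] * 2
    a <- logCPM(counts)
    b <- logCPM(doubled)
    # scaling a library changes its CPM column only through the prior
    expect_lt(max(abs(a[, -3] - b[, -3])), 1e-12)
    expect_lt(max(abs(2^a[, 3] - 2^b[, 3]) / 2^a[, 3]), 0.1)
})

test_that("activated-vs-homeostatic DE recovers the planted pattern", {
    sc <- simulateScCounts(simConfig(seed = 13))
    mg <- sc$cells$cellType == "microglia"
    pb <- pseudobulk(sc$counts[, mg], sc$cells[mg, ],
                     by = c("sample", "subcluster"), minCells = 5)
    de <- pseudobulkDE(pb, "subcluster", ref = "homeostatic")
    act <- de[de$gene %in% sc$truth$activation, ]
    hom <- de[de$gene %in% sc$truth$homeostatic, ]
    nul <- de[de$gene == sc$truth$nullGene, ]
    expect_true(all(act$logFC > 0 & act$q <= 0.05))
    expect_true(all(hom$logFC < 0 & hom$q <= 0.05))
    expect_gt(nul$q, 0.05)
})

test_that("cell-type specificity flags planted genes and only those", {
    sc <- simulateScCounts(simConfig(seed = 14))
    sp <- cellSpecificity(sc$counts, sc$cells, sc$truth$specific[1],
                          "microglia")
    expect_true(sp$selective)
    expect_equal(nrow(sp$table),
                 length(unique(sc$cells$cellType)) - 1L)
    pan <- cellSpecificity(sc$counts, sc$cells, sc$truth$panCellular[1],
                           "microglia")
    expect_false(pan$selective)
    expect_error(cellSpecificity(sc$counts, sc$cells, "absent-gene",
                                 "microglia"), "not found")
})

test_that("a gene with identical means everywhere is not selective", {
    set.seed(93)
    counts <- matrix(rpois(20 * 300, 5), nrow = 20,
                     dimnames = list(sprintf("g%02d", 1:20),
                                     sprintf("c%03d", 1:300)))
    cells <- data.frame(cell = colnames(counts),
                        sample = rep(paste0("s", 1:6), each = 50),
                        cellType = rep(c("mg", "ast", "neu"), 100))
    sp <- cellSpecificity(counts, cells, "g01", "mg", minCells = 1)
    expect_false(sp$selective)
    expect_true(all(abs(sp$table$log2Ratio) < 1))
})
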