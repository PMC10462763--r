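# Single-cell / single-nucleus stage: rank-based per-cell gene-set
# scoring, microglial subcluster labelling, pseudobulking by
# (sample, cell type), pseudobulk differential expression, and cell-type
# specificity testing. Cell matrices are sparse gene x cell count
# matrices (Matrix::dgCMatrix or dense) with a per-cell metadata
# data.frame carrying sample, group, cellType and subcluster labels.

.checkCells <- function(counts, cells, need = c("sample")) {
    pdAssert(ncol(counts) == nrow(cells),
             "cell metadata rows must match count columns")
    miss <- setdiff(need, colnames(cells))
    pdAssert(length(miss) == 0L,
             "missing cell label column(s): ", paste(miss, collapse = ", "))
    for (col in need)
        pdAssert(!anyNA(cells[[col]]), "cell label '", col, "' has NAs")
    invisible(TRUE)
}

#' AUC-style per-cell gene-set enrichment score
#'
#' For each cell, genes are ranked by decreasing count (ties broken by a
#' seeded random permutation, recorded per run) and the score is the area
#' under the recovery curve of gene-set members within the top
#' `ceiling(topFraction * G)` ranks, normalised by the maximum achievable
#' area; scores lie in [0, 1].
#'
#' @param counts gene x cell count matrix (sparse or dense, rownames =
#'   genes).
#' @param geneSet character vector of gene names; its intersection with
#'   the matrix genes must be non-empty.
#' @param topFraction fraction of the ranking considered (default 0.05).
#' @param seed seed for the tie-breaking permutation (default 1).
#' @param setName gene-set name recorded in the output.
#' @return data.frame: cell, geneSet, score.
#' @export
aucellScore <- function(counts, geneSet, topFraction = 0.05, seed = 1,
                        setName = "geneSet") {
    genes <- rownames(counts)
    pdAssert(!is.null(genes), "count matrix needs gene rownames")
    missing <- setdiff(geneSet, genes)
    inSet <- genes %in% geneSet
    pdAssert(any(inSet), "gene set has no overlap with the matrix; missing: ",
             paste(head(missing, 5), collapse = ", "))
    G <- length(genes)
    maxRank <- ceiling(topFraction * G)
    pdAssert(maxRank >= 1, "topFraction too small for the gene universe")
    nS <- sum(inSet)
    maxAUC <- sum(pmin(seq_len(maxRank), nS))
    tie <- withStreamSeed(seed, "aucell-ties", sample.int(G))
    cm <- as.matrix(counts)
    cellIds <- colnames(counts)
    if (is.null(cellIds)) cellIds <- as.character(seq_len(ncol(cm)))
    scores <- vapply(seq_len(ncol(cm)), function(j) {
        ord <- order(-cm[, j], tie)[seq_len(maxRank)]
        hits <- cumsum(inSet[ord])
        sum(hits) / maxAUC
    }, numeric(1))
    data.frame(cell = cellIds, geneSet = setName, score = scores,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Label subclusters by their dominant gene-set signature
#'
#' Each subcluster is assigned the gene set with the highest median
#' per-cell score, provided that set's scores beat every other set by a
#' two-sided rank-sum test at BH q <= 0.05 (adjusted over all tests);
#' otherwise the subcluster is labelled "ambiguous". The result does not
#' depend on subcluster order.
#'
#' @param scores data.frame with columns cell, geneSet, score, covering
#'   at least two gene sets (e.g. stacked [aucellScore()] outputs).
#' @param subcluster factor/character of subcluster labels per cell,
#'   named by cell or aligned with the unique cells in `scores`.
#' @param qCut significance cutoff (default 0.05).
#' @return data.frame: subcluster, label, topSet, worstQ.
#' @export
labelSubclusters <- function(scores, subcluster, qCut = 0.05) {
    cells <- unique(scores$cell)
    if (!is.null(names(subcluster))) subcluster <- subcluster[cells]
    pdAssert(length(subcluster) == length(cells),
             "subcluster labels must align with the scored cells")
    pdAssert(length(unique(subcluster)) >= 2L,
             "at least two subclusters are required")
    sets <- unique(scores$geneSet)
    pdAssert(length(sets) >= 2L, "at least two gene sets are required")
    sc <- split(scores, scores$geneSet)
    byCell <- lapply(sc, function(d) setNames(d$score, d$cell))
    subs <- sort(unique(as.character(subcluster)))
    recs <- list(); tests <- list()
    for (s in subs) {
        cellsIn <- cells[as.character(subcluster) == s]
        med <- vapply(sets, function(g) median(byCell[[g]][cellsIn]),
                      numeric(1))
        top <- sets[which.max(med)]
        ps <- vapply(setdiff(sets, top), function(g) {
            suppressWarnings(wilcox.test(byCell[[top]][cellsIn],
                                         byCell[[g]][cellsIn])$p.value)
        }, numeric(1))
        beats <- med[top] > med[setdiff(sets, top)]
        recs[[s]] <- list(top = top, ps = ps, beats = beats)
    }
    allP <- unlist(lapply(recs, `[[`, "ps"))
    allQ <- bhAdjust(allP)
    i <- 0L
    out <- lapply(subs, function(s) {
        r <- recs[[s]]
        q <- allQ[i + seq_along(r$ps)]
        i <<- i + length(r$ps)
        ok <- all(r$beats) && all(!is.na(q)) && all(q <= qCut)
        data.frame(subcluster = s,
                   label = if (ok) r$top else "ambiguous",
                   topSet = r$top,
                   worstQ = if (length(q)) max(q) else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Pseudobulk a cell matrix by (sample, cell type)
#'
#' Sums counts over the cells of each (sample, cell type) combination;
#' columns aggregating fewer cells than `minCells` are dropped (and
#' recorded). Returns a SummarizedExperiment with the summed counts and
#' per-column sample, cellType and nCells metadata.
#'
#' @param counts gene x cell count matrix (sparse or dense).
#' @param cells data.frame of per-cell labels with at least `sample` and
#'   `cellType` columns (extra columns such as `group` are carried over
#'   when constant within a pseudobulk column).
#' @param by character vector of grouping columns (default
#'   c("sample", "cellType")).
#' @param minCells minimum cells per retained column (default 10).
#' @return a `SummarizedExperiment` (assay "counts"); dropped columns are
#'   listed in `metadata(x)$dropped`.
#' @export
pseudobulk <- function(counts, cells, by = c("sample", "cellType"),
                       minCells = 10) {
    .checkCells(counts, cells, need = by)
    key <- interaction(cells[by], drop = TRUE, sep = ".", lex.order = TRUE)
    groups <- levels(key)
    agg <- vapply(groups, function(g) {
        Matrix::rowSums(counts[, key == g, drop = FALSE])
    }, numeric(nrow(counts)))
    agg <- matrix(agg, nrow = nrow(counts), dimnames = list(rownames(counts),
                                                            groups))
    nCells <- as.vector(table(key)[groups])
    cd <- unique(cbind(cells[by], key = as.character(key)))
    cd <- cd[match(groups, cd$key), , drop = FALSE]
    # carry over per-sample covariates that are constant within columns
    extra <- setdiff(colnames(cells), c(by, "key"))
    for (col in extra) {
        v <- tapply(as.character(cells[[col]]), key, function(x)
            if (length(unique(x)) == 1L) x[1L] else NA_character_)
        cd[[col]] <- as.character(v[groups])
    }
    cd$nCells <- nCells
    keep <- nCells >= minCells
    dropped <- groups[!keep]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = agg[, keep, drop = FALSE]),
        colData = S4Vectors::DataFrame(cd[keep, , drop = FALSE],
                                       row.names = groups[keep]))
    S4Vectors::metadata(se)$dropped <- dropped
    S4Vectors::metadata(se)$minCells <- minCells
    se
}

#' Differential expression on pseudobulk columns
#'
#' Transforms the summed counts to log2 CPM (prior 0.5) and fits, per
#' gene, the same two-group ordinary-least-squares model as
#' [perDatasetDE()] on the requested contrast column of the pseudobulk
#' column metadata; p-values are BH adjusted across genes.
#'
#' @param pb a `SummarizedExperiment` from [pseudobulk()].
#' @param contrast name of a two-level colData column (e.g. "group" or
#'   "subcluster").
#' @param ref optional reference (control) level; default the first level
#'   alphabetically.
#' @param cellType optional: restrict columns to one cell type first.
#' @return data.frame as from [perDatasetDE()].
#' @export
pseudobulkDE <- function(pb, contrast, ref = NULL, cellType = NULL) {
    cd <- as.data.frame(SummarizedExperiment::colData(pb))
    counts <- SummarizedExperiment::assay(pb, "counts")
    if (!is.null(cellType)) {
        keep <- cd$cellType == cellType
        cd <- cd[keep, , drop = FALSE]
        counts <- counts[, keep, drop = FALSE]
    }
    pdAssert(contrast %in% colnames(cd), "unknown contrast column: ", contrast)
    lab <- as.character(cd[[contrast]])
    lv <- sort(unique(lab))
    pdAssert(length(lv) == 2L, "contrast must have exactly two levels, got ",
             length(lv))
    if (!is.null(ref)) {
        pdAssert(ref %in% lv, "reference level not found")
        lv <- c(ref, setdiff(lv, ref))
    }
    pdAssert(min(table(lab)) >= 2L,
             "each contrast level needs at least 2 pseudobulk columns")
    cond <- factor(lab, levels = lv)
    # reuse the vectorised OLS core; the >=3 replicate floor of
    # DatasetExpression does not apply to pseudobulk contrasts
    x <- logCPM(counts, prior = 0.5)
    g1 <- cond == lv[1L]; g2 <- !g1
    n1 <- sum(g1); n2 <- sum(g2)
    m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, g2, drop = FALSE])
    ss <- rowSums((x[, g1, drop = FALSE] - m1)^2) +
          rowSums((x[, g2, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2
    se <- pmax(sqrt(ss / df * (1 / n1 + 1 / n2)), 1e-8)
    logFC <- m2 - m1
    p <- 2 * pt(-abs(logFC / se), df = df)
    data.frame(dataset = paste0("pseudobulk.", contrast), gene = rownames(x),
               logFC = logFC, se = se, df = df, p = p, q = bhAdjust(p),
               note = "", row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-type specificity of a gene
#'
#' Pseudobulks per (sample, cell type), then compares the target cell
#' type against every other type using the per-sample log2 CPM ratio
#' (paired by sample) and a two-sided one-sample rank-sum (signed-rank)
#' test; the gene is flagged selective when the mean fold change is at
#' least `foldCut` against every other type with BH q <= `qCut`.
#'
#' @param counts gene x cell count matrix.
#' @param cells per-cell label data.frame with `sample` and `cellType`.
#' @param gene gene to test (must be present).
#' @param targetType the cell type the gene should be selective for.
#' @param foldCut fold-change threshold (default 4).
#' @param qCut BH q cutoff (default 0.05).
#' @param minCells pseudobulk column floor (default 10).
#' @return list with `selective` (logical) and `table`: one row per other
#'   cell type (otherType, nPairs, log2Ratio, fold, p, q, pass).
#' @export
cellSpecificity <- function(counts, cells, gene, targetType, foldCut = 4,
                            qCut = 0.05, minCells = 10) {
    pdAssert(gene %in% rownames(counts), "gene not found: ", gene)
    .checkCells(counts, cells, need = c("sample", "cellType"))
    types <- unique(as.character(cells$cellType))
    pdAssert(length(types) >= 2L, "at least two cell types are required")
    pdAssert(targetType %in% types, "target cell type not found: ", targetType)
    pb <- pseudobulk(counts, cells[c("sample", "cellType")],
                     minCells = minCells)
    cd <- as.data.frame(SummarizedExperiment::colData(pb))
    x <- logCPM(SummarizedExperiment::assay(pb, "counts"), prior = 0.5)
    gx <- x[gene, ]
    tgt <- setNames(gx[cd$cellType == targetType],
                    cd$sample[cd$cellType == targetType])
    rows <- lapply(setdiff(types, targetType), function(ot) {
        oth <- setNames(gx[cd$cellType == ot], cd$sample[cd$cellType == ot])
        shared <- intersect(names(tgt), names(oth))
        ratios <- tgt[shared] - oth[shared]
        p <- if (length(shared) >= 1L && any(ratios != 0))
            suppressWarnings(wilcox.test(ratios, mu = 0)$p.value) else 1
        data.frame(otherType = ot, nPairs = length(shared),
                   log2Ratio = mean(ratios), fold = 2^mean(ratios), p = p,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- bhAdjust(tab$p)
    tab$pass <- tab$fold >= foldCut & tab$q <= qCut
    list(gene = gene, targetType = targetType,
         selective = all(tab$pass), table = tab)
}
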