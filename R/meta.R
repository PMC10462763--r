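# Per-dataset differential expression and DerSimonian-Laird random-effects
# meta-analysis. Count datasets are transformed to log2 CPM (prior 0.5)
# before modelling; the per-gene model is ordinary least squares of log2
# expression on the two-level condition, vectorised across genes.

#' Per-dataset differential expression
#'
#' Fits, per gene, ordinary least squares of log2 expression on the
#' condition label. logFC is the condition coefficient (stimulated minus
#' control, i.e. second factor level minus first), with its standard
#' error and two-sided t-test p-value on the residual degrees of freedom;
#' p-values are BH adjusted within the dataset. Count matrices are first
#' transformed to log2 counts-per-million with prior count 0.5.
#'
#' @param ds a [DatasetExpression-class].
#' @param genes optional character vector restricting the genes tested.
#' @param seFloor lower guard on the standard error (default 1e-8) so
#'   noise-free data do not produce zero SEs.
#' @return data.frame: dataset, gene, logFC, se, df, p, q, note. Genes
#'   with fewer than 2 usable samples in a condition get NA statistics
#'   and a reason in `note`.
#' @export
perDatasetDE <- function(ds, genes = NULL, seFloor = 1e-8) {
    pdAssert(is(ds, "DatasetExpression"), "ds must be a DatasetExpression")
    x <- ds@exprs
    if (ds@platform == "counts") x <- logCPM(x, prior = 0.5)
    if (!is.null(genes)) {
        pdAssert(all(genes %in% rownames(x)), "unknown genes requested")
        x <- x[genes, , drop = FALSE]
    }
    g1 <- ds@condition == levels(ds@condition)[1L]
    g2 <- !g1
    ok <- !is.na(x)
    n1 <- rowSums(ok[, g1, drop = FALSE])
    n2 <- rowSums(ok[, g2, drop = FALSE])
    s1 <- rowSums(x[, g1, drop = FALSE] * ok[, g1, drop = FALSE], na.rm = TRUE)
    s2 <- rowSums(x[, g2, drop = FALSE] * ok[, g2, drop = FALSE], na.rm = TRUE)
    m1 <- s1 / n1; m2 <- s2 / n2
    ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2, na.rm = TRUE)
    ss2 <- rowSums((x[, g2, drop = FALSE] - m2)^2, na.rm = TRUE)
    df <- n1 + n2 - 2
    sp2 <- (ss1 + ss2) / pmax(df, 1)
    logFC <- m2 - m1
    se <- pmax(sqrt(sp2 * (1 / n1 + 1 / n2)), seFloor)
    p <- 2 * pt(-abs(logFC / se), df = df)
    bad <- n1 < 2 | n2 < 2
    note <- ifelse(bad, "fewer than 2 samples in a condition", "")
    logFC[bad] <- NA; se[bad] <- NA; p[bad] <- NA; df[bad] <- NA
    data.frame(dataset = ds@id, gene = rownames(x), logFC = logFC, se = se,
               df = df, p = p, q = bhAdjust(p), note = note,
               row.names = NULL, stringsAsFactors = FALSE)
}

# vectorised DerSimonian-Laird over genes: Y and SE are genes x k matrices
.dlCore <- function(Y, SE, ciMult = 1.96) {
    k <- ncol(Y)
    W <- 1 / SE^2
    sw <- rowSums(W)
    fixed <- rowSums(W * Y) / sw
    Q <- rowSums(W * (Y - fixed)^2)
    denom <- sw - rowSums(W^2) / sw
    tau2 <- pmax(0, (Q - (k - 1)) / denom)
    if (k == 1L) tau2 <- rep(0, nrow(Y))
    Ws <- 1 / (SE^2 + tau2)
    pooled <- rowSums(Ws * Y) / rowSums(Ws)
    se <- sqrt(1 / rowSums(Ws))
    seFixed <- sqrt(1 / sw)
    I2 <- ifelse(Q > 0, pmax(0, (Q - (k - 1)) / Q), 0)
    p <- 2 * pnorm(-abs(pooled / se))
    data.frame(k = k, logFC = pooled, se = se,
               ciLow = pooled - ciMult * se, ciHigh = pooled + ciMult * se,
               tau2 = tau2, Q = Q, I2 = I2, p = p,
               seFixed = seFixed, stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects meta-analysis for one gene
#'
#' Moment estimator of the between-study variance: with weights
#' `w_i = 1/SE_i^2`, `Q = sum w_i (y_i - ybar)^2` and
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; the pooled
#' estimate uses random-effects weights `1/(SE_i^2 + tau^2)`, a 1.96
#' multiplier for the 95% CI, and a normal-approximation p-value.
#'
#' @param y numeric vector of per-dataset effects (log2 fold changes).
#' @param se positive standard errors, same length.
#' @param ciMult CI multiplier (default 1.96 for 95%).
#' @return one-row data.frame: k, logFC (pooled), se, ciLow, ciHigh,
#'   tau2, Q, I2, p, seFixed.
#' @examples
#' dlMeta(c(1, 0), c(0.5, 0.5))
#' @export
dlMeta <- function(y, se, ciMult = 1.96) {
    pdAssert(length(y) >= 1L, "at least one effect estimate is required")
    pdAssert(length(y) == length(se), "y and se must have equal length")
    pdAssert(all(is.finite(y)) && all(is.finite(se)), "effects must be finite")
    pdAssert(all(se > 0), "all standard errors must be positive")
    .dlCore(matrix(y, nrow = 1), matrix(se, nrow = 1), ciMult = ciMult)
}

#' Cross-dataset random-effects meta-analysis
#'
#' Aligns per-dataset effect tables by gene, pools each gene with the
#' DerSimonian-Laird estimator, and BH-adjusts the meta p-values across
#' genes. Genes with NA effects in a dataset are pooled over the
#' remaining datasets (k varies per gene).
#'
#' @param effects list of data.frames as returned by [perDatasetDE()]
#'   (columns gene, logFC, se), or one long data.frame with a `dataset`
#'   column.
#' @param ciMult CI multiplier (default 1.96).
#' @return data.frame keyed by gene: gene, k, logFC, se, ciLow, ciHigh,
#'   tau2, Q, I2, p, q, seFixed.
#' @export
metaAnalysis <- function(effects, ciMult = 1.96) {
    if (is.data.frame(effects))
        effects <- split(effects, effects$dataset)
    pdAssert(length(effects) >= 1L, "at least one dataset is required")
    genes <- sort(unique(unlist(lapply(effects, `[[`, "gene"))))
    k <- length(effects)
    Y <- SE <- matrix(NA_real_, nrow = length(genes), ncol = k)
    for (j in seq_len(k)) {
        e <- effects[[j]]
        i <- match(e$gene, genes)
        Y[i, j] <- e$logFC
        SE[i, j] <- e$se
    }
    pdAssert(all(SE > 0, na.rm = TRUE), "all standard errors must be positive")
    used <- is.finite(Y) & is.finite(SE)
    kg <- rowSums(used)
    pdAssert(all(kg >= 1), "every gene needs at least one usable estimate")
    # vectorise over the common full-k case, loop the ragged remainder
    res <- vector("list", length(genes))
    full <- kg == k
    if (any(full)) {
        r <- .dlCore(Y[full, , drop = FALSE], SE[full, , drop = FALSE],
                     ciMult = ciMult)
        res[which(full)] <- split(r, seq_len(nrow(r)))
    }
    for (i in which(!full)) {
        u <- used[i, ]
        res[[i]] <- .dlCore(matrix(Y[i, u], nrow = 1),
                            matrix(SE[i, u], nrow = 1), ciMult = ciMult)
    }
    out <- do.call(rbind, res)
    out <- cbind(gene = genes, out, stringsAsFactors = FALSE)
    out$k <- kg
    out$q <- bhAdjust(out$p)
    rownames(out) <- NULL
    out
}

#' Long-format forest-plot table
#'
#' One row per (gene, dataset) effect plus one pooled row per gene, with
#' 95% CI bounds, suitable for forest plotting or TSV export.
#'
#' @param meta data.frame from [metaAnalysis()].
#' @param effects list (or long data.frame) of per-dataset effect tables.
#' @param ciMult CI multiplier for the per-dataset rows (default 1.96).
#' @return data.frame: gene, source ("pooled" or dataset id), logFC, se,
#'   ciLow, ciHigh, p, q (pooled rows only).
#' @export
forestTable <- function(meta, effects, ciMult = 1.96) {
    if (is.data.frame(effects)) effects <- split(effects, effects$dataset)
    pdAssert(nrow(meta) >= 1L, "meta table must contain at least one gene")
    per <- do.call(rbind, lapply(effects, function(e) {
        e <- e[e$gene %in% meta$gene & is.finite(e$logFC), , drop = FALSE]
        data.frame(gene = e$gene, source = e$dataset, logFC = e$logFC,
                   se = e$se, ciLow = e$logFC - ciMult * e$se,
                   ciHigh = e$logFC + ciMult * e$se, p = e$p, q = NA_real_,
                   stringsAsFactors = FALSE)
    }))
    pooled <- data.frame(gene = meta$gene, source = "pooled",
                         logFC = meta$logFC, se = meta$se,
                         ciLow = meta$ciLow, ciHigh = meta$ciHigh,
                         p = meta$p, q = meta$q, stringsAsFactors = FALSE)
    out <- rbind(per, pooled)
    out <- out[order(out$gene, out$source == "pooled", out$source), ]
    rownames(out) <- NULL
    out
}
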