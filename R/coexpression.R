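# Signed-hybrid weighted co-expression networks: soft-threshold
# selection by scale-free topology fit, topological overlap similarity,
# module detection by average-linkage clustering of the TOM
# dissimilarity with a static height cut and minimum module size, and
# hypergeometric module overlap with a random-module baseline.

#' Expression filter for network analysis
#'
#' Keeps genes with an expression value of at least `minValue` in at
#' least `minFraction` of samples.
#'
#' @param expr genes x samples matrix.
#' @param minValue count/expression threshold (default 1).
#' @param minFraction fraction of samples (default 0.5).
#' @return the filtered matrix.
#' @export
filterExpressed <- function(expr, minValue = 1, minFraction = 0.5) {
    keep <- rowMeans(expr >= minValue) >= minFraction
    expr[keep, , drop = FALSE]
}

#' Signed-hybrid adjacency matrix
#'
#' `a_ij = cor(i, j)^beta` for positive Pearson correlations and 0
#' otherwise (negative correlations carry no edge); the diagonal is 0.
#'
#' @param expr genes x samples matrix (no constant genes).
#' @param beta soft-threshold power (integer >= 1).
#' @return gene x gene adjacency matrix.
#' @export
signedHybridAdjacency <- function(expr, beta) {
    pdAssert(beta >= 1, "beta must be >= 1")
    sds <- apply(expr, 1, sd)
    pdAssert(all(sds > 0), "constant genes must be removed first")
    r <- cor(t(expr))
    a <- ifelse(r > 0, r^beta, 0)
    diag(a) <- 0
    a
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the signed-hybrid adjacency, computes
#' per-gene connectivity `k_i = sum_j a_ij`, bins log10 connectivity into
#' `nBins` bins and regresses log10 frequency on the log10 bin mean; the
#' fit R^2 is the scale-free topology criterion. Returns the minimum
#' power whose R^2 meets the target, or the argmax power with a warning
#' when none does. Constant genes are removed first (and recorded).
#'
#' @param expr genes x samples matrix (>= 20 genes, >= 8 samples).
#' @param powers candidate powers (default 1:20).
#' @param rsqTarget target fit R^2 (default 0.85).
#' @param nBins connectivity bins (default 10).
#' @return list: beta, fitTable (power, rsq, slope, meanK), reached,
#'   removedGenes.
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, rsqTarget = 0.85,
                              nBins = 10) {
    pdAssert(nrow(expr) >= 20, "need at least 20 genes")
    pdAssert(ncol(expr) >= 8, "need at least 8 samples")
    sds <- apply(expr, 1, sd)
    removed <- rownames(expr)[sds == 0]
    expr <- expr[sds > 0, , drop = FALSE]
    r <- cor(t(expr))
    rp <- ifelse(r > 0, r, 0)
    diag(rp) <- 0
    fit <- lapply(powers, function(b) {
        k <- colSums(rp^b)
        sfFit(k, nBins = nBins)
    })
    tab <- data.frame(power = powers,
                      rsq = vapply(fit, `[[`, numeric(1), "rsq"),
                      slope = vapply(fit, `[[`, numeric(1), "slope"),
                      meanK = vapply(fit, `[[`, numeric(1), "meanK"))
    # scale-free topology means a *decaying* degree distribution, so a
    # power only qualifies when the log-log slope is negative
    ok <- which(tab$rsq >= rsqTarget & tab$slope < 0)
    if (length(ok)) {
        beta <- powers[min(ok)]
        reached <- TRUE
    } else {
        neg <- tab$slope < 0
        beta <- if (any(neg)) powers[neg][which.max(tab$rsq[neg])]
                else powers[which.max(tab$rsq)]
        reached <- FALSE
        warning("no power reached the scale-free fit target; returning ",
                "the best-fitting power ", beta)
    }
    list(beta = beta, fitTable = tab, reached = reached,
         removedGenes = removed)
}

# scale-free topology fit of a connectivity vector
sfFit <- function(k, nBins = 10) {
    k <- k[k > 0]
    if (length(unique(k)) < 3)
        return(list(rsq = 0, slope = 0, meanK = mean(k)))
    br <- seq(min(k), max(k), length.out = nBins + 1)  # equal-width bins
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    mid <- tapply(k, bin, mean)
    keep <- !is.na(freq) & freq > 0 & mid > 0
    if (sum(keep) < 3)
        return(list(rsq = 0, slope = 0, meanK = mean(k)))
    f <- lm(log10(freq[keep]) ~ log10(mid[keep]))
    list(rsq = summary(f)$r.squared, slope = unname(coef(f)[2]),
         meanK = mean(k))
}

#' Topological overlap similarity matrix
#'
#' From a signed-hybrid adjacency:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; symmetric with entries in [0, 1].
#'
#' @param adj adjacency matrix from [signedHybridAdjacency()].
#' @return TOM similarity matrix.
#' @export
tomSimilarity <- function(adj) {
    pdAssert(isSymmetric(unname(adj)), "adjacency must be symmetric")
    k <- colSums(adj)
    num <- adj %*% adj + adj
    den <- outer(k, k, pmin) + 1 - adj
    tom <- num / den
    diag(tom) <- 1
    dimnames(tom) <- dimnames(adj)
    tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' `1 - TOM`, cut at a static height; clusters smaller than the minimum
#' module size are merged into module 0 (unassigned). Modules are
#' relabelled 1, 2, ... by decreasing size, ties broken by first gene
#' order.
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param cutHeight static tree-cut height (default 0.95).
#' @param minModuleSize minimum genes per module (default 30).
#' @return list: modules (named integer vector, 0 = unassigned), sizes
#'   (table over module ids > 0), dendro (the hclust object).
#' @export
detectModules <- function(tom, cutHeight = 0.95, minModuleSize = 30) {
    d <- as.dist(1 - tom)
    h <- hclust(d, method = "average")
    raw <- cutree(h, h = cutHeight)
    tab <- table(raw)
    keep <- names(tab)[tab >= minModuleSize]
    mod <- ifelse(raw %in% as.integer(keep), raw, 0L)
    # relabel by decreasing size, ties by first gene occurrence
    tabPos <- table(mod[mod != 0L])
    if (length(tabPos)) {
        firstOcc <- vapply(names(tabPos),
                           function(id) which(mod == as.integer(id))[1L],
                           numeric(1))
        ids <- names(tabPos)[order(-as.vector(tabPos), firstOcc)]
        newId <- setNames(seq_along(ids), ids)
        out <- ifelse(mod == 0L, 0L, as.integer(newId[as.character(mod)]))
    } else out <- rep(0L, length(mod))
    names(out) <- rownames(tom)
    list(modules = out, sizes = table(out[out != 0L]), dendro = h)
}

#' Module of a target gene
#'
#' @param modules named module vector from [detectModules()].
#' @param gene target gene name.
#' @return character vector of the genes sharing the target's module
#'   (empty if the target is unassigned).
#' @export
moduleOf <- function(modules, gene) {
    pdAssert(gene %in% names(modules), "gene not in module assignment: ", gene)
    id <- modules[[gene]]
    if (id == 0L) return(character(0))
    names(modules)[modules == id]
}

#' Overlap of two gene modules with a hypergeometric test
#'
#' Reports the intersection size, a one-sided hypergeometric tail
#' p-value, and a size-matched random-module baseline (seeded draws of
#' the same sizes from the universe) with its null mean overlap.
#'
#' @param moduleA,moduleB character vectors of genes; both must be
#'   subsets of `universe` (any ortholog-name harmonisation is the
#'   caller's responsibility).
#' @param universe character vector of all eligible genes.
#' @param nullDraws random-module draws for the baseline (default 1000).
#' @param seed seed for the baseline draws.
#' @return list: overlap, genes, p, expected (|A||B|/|U|), nullMean,
#'   nullDraws.
#' @export
moduleOverlap <- function(moduleA, moduleB, universe, nullDraws = 1000,
                          seed = 1) {
    pdAssert(length(universe) >= 1L, "universe must be non-empty")
    pdAssert(all(moduleA %in% universe) && all(moduleB %in% universe),
             "modules must be subsets of the universe")
    moduleA <- unique(moduleA); moduleB <- unique(moduleB)
    ov <- length(intersect(moduleA, moduleB))
    U <- length(unique(universe))
    nA <- length(moduleA); nB <- length(moduleB)
    p <- phyper(ov - 1, nA, U - nA, nB, lower.tail = FALSE)
    nullMean <- withStreamSeed(seed, "module-overlap-null", {
        mean(vapply(seq_len(nullDraws), function(i) {
            a <- sample(U, nA); b <- sample(U, nB)
            length(intersect(a, b))
        }, numeric(1)))
    })
    list(overlap = ov, genes = intersect(moduleA, moduleB), p = p,
         expected = nA * nB / U, nullMean = nullMean,
         nullDraws = nullDraws)
}
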