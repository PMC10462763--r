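# Maximum-parsimony inference on promoter alignments.
#
# Alignments are named character vectors (or DNAStringSet / list) of
# equal-length gapped sequences over A, C, G, T, N, '-'. Gaps and N are
# treated as missing data: they can take any state and contribute no
# changes. Sites are compressed to unique patterns with weights; Fitch
# counting works on bit-encoded states (A=1, C=2, G=4, T=8, missing=15)
# so the per-site intersection/union steps vectorise over patterns.

.alnCodes <- function(aln) {
    if (is(aln, "DNAStringSet")) aln <- as.character(aln)
    if (is.list(aln)) aln <- unlist(aln)
    pdAssert(!is.null(names(aln)) && !anyDuplicated(names(aln)),
             "alignment sequences must have unique names")
    lens <- nchar(aln)
    pdAssert(length(unique(lens)) == 1L,
             "alignment rows must all have equal length")
    chmat <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
    map <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, "-" = 15L, "?" = 15L)
    code <- matrix(map[chmat], nrow = nrow(chmat))
    code[is.na(code)] <- 15L
    rownames(code) <- names(aln)
    code
}

# compress site columns to unique patterns with weights
.alnPatterns <- function(code) {
    key <- apply(code, 2, paste, collapse = ",")
    ukey <- key[!duplicated(key)]
    idx <- match(key, ukey)
    pat <- code[, !duplicated(key), drop = FALSE]
    w <- tabulate(idx, nbins = length(ukey))
    list(labels = rownames(code), pat = pat, w = w, siteIndex = idx)
}

# --- unrooted tree as adjacency lists -------------------------------------
# nodes: 1..n are leaves (row order of the alignment), internal nodes > n.
# nb[[v]] is the integer vector of neighbours of v (NULL if unused).

.edgeList <- function(nb) {
    out <- matrix(0L, nrow = 0L, ncol = 2L)
    for (v in seq_along(nb)) {
        us <- nb[[v]]
        if (is.null(us)) next
        us <- us[us > v]
        if (length(us))
            out <- rbind(out, cbind(v, us, deparse.level = 0))
    }
    out
}

.replaceNb <- function(nb, v, from, to) {
    x <- nb[[v]]
    x[x == from] <- to
    nb[[v]] <- x
    nb
}

# attach leaf t to edge (u,v) via new internal node w
.attachLeaf <- function(nb, u, v, t, w) {
    nb <- .replaceNb(nb, u, v, w)
    nb <- .replaceNb(nb, v, u, w)
    nb[[w]] <- c(u, v, t)
    nb[[t]] <- w
    nb
}

# Fitch per-pattern change counts, rooted at leaf `rootLeaf`
.fitchCounts <- function(nb, pat, rootLeaf) {
    n <- nrow(pat)
    start <- nb[[rootLeaf]][1L]
    # traversal order (preorder) with parents
    nodes <- integer(0); pars <- integer(0)
    S <- start; P <- rootLeaf; i <- 1L
    while (i <= length(S)) {
        v <- S[i]; p <- P[i]
        nodes <- c(nodes, v); pars <- c(pars, p)
        for (u in nb[[v]]) if (u != p) { S <- c(S, u); P <- c(P, v) }
        i <- i + 1L
    }
    changes <- numeric(ncol(pat))
    state <- vector("list", length(nb))
    for (k in rev(seq_along(nodes))) {
        v <- nodes[k]
        if (v <= n) { state[[v]] <- pat[v, ]; next }
        kids <- nb[[v]][nb[[v]] != pars[k]]
        s <- state[[kids[1L]]]
        for (u in kids[-1L]) {
            su <- state[[u]]
            t <- bitwAnd(s, su)
            z <- t == 0L
            if (any(z)) {
                t[z] <- bitwOr(s[z], su[z])
                changes[z] <- changes[z] + 1
            }
            s <- t
        }
        state[[v]] <- s
    }
    z <- bitwAnd(pat[rootLeaf, ], state[[start]]) == 0L
    changes[z] <- changes[z] + 1
    changes
}

# greedy stepwise addition in the given taxon order
.additionTree <- function(pats, order) {
    pat <- pats$pat; w <- pats$w
    n <- nrow(pat)
    nb <- vector("list", 2L * n - 2L)
    t1 <- order[1L]; t2 <- order[2L]; t3 <- order[3L]
    c0 <- n + 1L
    nb[[c0]] <- c(t1, t2, t3)
    nb[[t1]] <- c0; nb[[t2]] <- c0; nb[[t3]] <- c0
    nexti <- n + 2L
    if (length(order) > 3L) for (t in order[4:length(order)]) {
        edges <- .edgeList(nb)
        best <- Inf; bestNb <- NULL
        for (e in seq_len(nrow(edges))) {
            cand <- .attachLeaf(nb, edges[e, 1L], edges[e, 2L], t, nexti)
            len <- sum(.fitchCounts(cand, pat, order[1L]) * w)
            if (len < best) { best <- len; bestNb <- cand }
        }
        nb <- bestNb
        nexti <- nexti + 1L
    }
    nb
}

# split at edge (u,v); returns component adjacency (suppressed), its edge
# list, the node freed by suppression (0 if none) and a single-leaf flag
.splitComponent <- function(nb, u, v, n) {
    nb <- .replaceNb(nb, u, v, 0L)
    nb[[u]] <- nb[[u]][nb[[u]] != 0L]
    if (u <= n && length(nb[[u]]) == 0L) {
        return(list(nb = nb, leaf = u, freed = 0L, single = TRUE))
    }
    freed <- 0L
    start <- u
    if (length(nb[[u]]) == 2L) {  # suppress degree-2 node
        xy <- nb[[u]]
        nb <- .replaceNb(nb, xy[1L], u, xy[2L])
        nb <- .replaceNb(nb, xy[2L], u, xy[1L])
        nb[u] <- list(NULL)  # keep the slot; [[<- NULL would shift ids
        freed <- u
        start <- xy[1L]  # u is gone; enter the component at an ex-neighbour
    }
    comp <- start; i <- 1L
    seen <- rep(FALSE, length(nb)); seen[start] <- TRUE
    while (i <= length(comp)) {
        for (x in nb[[comp[i]]]) if (!seen[x]) { seen[x] <- TRUE; comp <- c(comp, x) }
        i <- i + 1L
    }
    edges <- matrix(0L, 0L, 2L)
    for (a in comp) {
        bs <- nb[[a]]; bs <- bs[bs > a & seen[bs]]
        if (length(bs)) edges <- rbind(edges, cbind(a, bs, deparse.level = 0))
    }
    list(nb = nb, nodes = comp, edges = edges, freed = freed, single = FALSE)
}

# one first-improvement TBR sweep; returns improved tree or NULL
.tbrImprove <- function(nb, pats, curLen, rootLeaf) {
    pat <- pats$pat; w <- pats$w
    n <- nrow(pat)
    edges <- .edgeList(nb)
    for (e in seq_len(nrow(edges))) {
        u <- edges[e, 1L]; v <- edges[e, 2L]
        base <- nb
        A <- .splitComponent(base, u, v, n)
        B <- .splitComponent(A$nb, v, u, n)
        nb2 <- B$nb
        freeIds <- c(A$freed, B$freed)
        freeIds <- freeIds[freeIds != 0L]
        aEdges <- if (A$single) matrix(c(A$leaf, 0L), 1L) else A$edges
        bEdges <- if (B$single) matrix(c(B$leaf, 0L), 1L) else B$edges
        for (ia in seq_len(nrow(aEdges))) for (ib in seq_len(nrow(bEdges))) {
            cand <- nb2
            free <- freeIds
            if (A$single) {
                pa <- A$leaf
            } else {
                pa <- free[1L]; free <- free[-1L]
                x <- aEdges[ia, 1L]; y <- aEdges[ia, 2L]
                cand <- .replaceNb(cand, x, y, pa)
                cand <- .replaceNb(cand, y, x, pa)
                cand[[pa]] <- c(x, y)
            }
            if (B$single) {
                pb <- B$leaf
            } else {
                pb <- free[1L]
                x <- bEdges[ib, 1L]; y <- bEdges[ib, 2L]
                cand <- .replaceNb(cand, x, y, pb)
                cand <- .replaceNb(cand, y, x, pb)
                cand[[pb]] <- c(x, y)
            }
            cand[[pa]] <- c(cand[[pa]], pb)
            cand[[pb]] <- c(cand[[pb]], pa)
            len <- sum(.fitchCounts(cand, pat, rootLeaf) * w)
            if (len < curLen) return(list(nb = cand, len = len))
        }
    }
    NULL
}

# Newick string from adjacency; canonical = rooted at the alphabetically
# first taxon with children sorted by subtree string
.nbNewick <- function(nb, labels, canonical = TRUE) {
    n <- length(labels)
    rootLeaf <- if (canonical) order(labels)[1L] else 1L
    rec <- function(v, p) {
        if (v <= n) return(labels[v])
        ss <- vapply(nb[[v]][nb[[v]] != p], rec, character(1), p = v)
        if (canonical) ss <- sort(ss)
        paste0("(", paste(ss, collapse = ","), ")")
    }
    start <- nb[[rootLeaf]][1L]
    paste0("(", labels[rootLeaf], ",", rec(start, rootLeaf), ");")
}

# ape phylo -> adjacency, remapping tips to alignment row order
.phyloToNb <- function(tree, labels) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    pdAssert(inherits(tree, "phylo"), "topology must be a phylo or Newick")
    pdAssert(setequal(tree$tip.label, labels),
             "topology leaf set must equal the alignment taxa")
    tree <- ape::unroot(tree)
    n <- length(labels)
    tipMap <- match(tree$tip.label, labels)
    mapId <- function(x) ifelse(x <= n, tipMap[x], x)
    nb <- vector("list", n + tree$Nnode)
    for (i in seq_len(nrow(tree$edge))) {
        a <- mapId(tree$edge[i, 1L]); b <- mapId(tree$edge[i, 2L])
        nb[[a]] <- c(nb[[a]], b)
        nb[[b]] <- c(nb[[b]], a)
    }
    nb
}

#' Fitch parsimony length of a topology on an alignment
#'
#' Sums over sites the minimum number of state changes under Fitch
#' counting. Gaps and N are missing data (any state, zero cost). The
#' result is invariant to leaf order and rooting.
#'
#' @param aln named character vector (or DNAStringSet) of equal-length
#'   aligned sequences.
#' @param tree an `ape::phylo` or Newick string whose leaf set equals the
#'   alignment taxa.
#' @return integer total site changes.
#' @examples
#' aln <- c(s1 = "AA", s2 = "AC", s3 = "CA", s4 = "CC")
#' fitchLength(aln, "((s1,s2),(s3,s4));")
#' @export
fitchLength <- function(aln, tree) {
    code <- .alnCodes(aln)
    pats <- .alnPatterns(code)
    nb <- .phyloToNb(tree, pats$labels)
    as.integer(sum(.fitchCounts(nb, pats$pat, 1L) * pats$w))
}

# shared core: hill-climbed search returning adjacency + length
.tbrCore <- function(pats, restarts, seed) {
    n <- nrow(pats$pat)
    labOrd <- order(pats$labels)  # taxon-order invariance: map by label
    rootLeaf <- labOrd[1L]
    bestLen <- Inf; bestNb <- NULL; bestKey <- NULL; moves <- 0L
    for (r in seq_len(restarts)) {
        ord <- labOrd[sample.int(n)]
        nb <- .additionTree(pats, ord)
        len <- sum(.fitchCounts(nb, pats$pat, rootLeaf) * pats$w)
        repeat {
            imp <- .tbrImprove(nb, pats, len, rootLeaf)
            if (is.null(imp)) break
            nb <- imp$nb; len <- imp$len; moves <- moves + 1L
        }
        key <- .nbNewick(nb, pats$labels, canonical = TRUE)
        if (len < bestLen || (len == bestLen && key < bestKey)) {
            bestLen <- len; bestNb <- nb; bestKey <- key
        }
    }
    list(nb = bestNb, len = bestLen, key = bestKey, moves = moves)
}

#' Heuristic maximum-parsimony search with TBR rearrangements
#'
#' Hill-climbs from random-addition starting trees, accepting strictly
#' shorter neighbours under tree-bisection-reconnection moves
#' (first-improvement), and returns the shortest tree found. Ties among
#' equally short trees are broken by the lexicographically smallest
#' canonical Newick string. Deterministic given the seed; taxon input
#' order does not matter because the random addition order is mapped by
#' label.
#'
#' @param aln named character vector (or DNAStringSet) of equal-length
#'   aligned sequences; at least 4 taxa.
#' @param restarts number of random-addition restarts (>= 1, default 10).
#' @param seed integer random seed.
#' @param computeIndices also compute CI/RI (default TRUE).
#' @return a [ParsimonyTree-class].
#' @export
tbrSearch <- function(aln, restarts = 10, seed = 1, computeIndices = TRUE) {
    pdAssert(restarts >= 1, "restarts must be >= 1")
    code <- .alnCodes(aln)
    pdAssert(nrow(code) >= 4L, "tree search needs at least 4 taxa")
    pats <- .alnPatterns(code)
    res <- withStreamSeed(seed, "tbr", .tbrCore(pats, restarts, seed))
    phy <- ape::read.tree(text = .nbNewick(res$nb, pats$labels))
    idx <- if (computeIndices)
        .ciRiCore(pats, res$len,
                  perPattern = .fitchCounts(res$nb, pats$pat, 1L))
    else list(ci = NA_real_, ri = NA_real_,
              ciInf = NA_real_, riInf = NA_real_)
    new("ParsimonyTree", tree = phy, score = as.integer(res$len),
        ci = idx$ci, ri = idx$ri,
        ciInformative = idx$ciInf, riInformative = idx$riInf,
        metadata = list(restarts = restarts, seed = seed,
                        movesAccepted = res$moves,
                        gapHandling = "missing",
                        tieBreak = "canonical-newick"))
}

# CI/RI from compressed patterns and an observed length; the informative
# variants restrict all three sums to parsimony-informative sites
.ciRiCore <- function(pats, L, perPattern = NULL) {
    pat <- pats$pat; w <- pats$w
    stats <- apply(pat, 2, function(col) {
        obs <- col[col != 15L]
        if (!length(obs)) return(c(m = 0, g = 0, inf = 0))
        tab <- table(obs)
        k <- length(tab)
        c(m = k - 1, g = length(obs) - max(tab),
          inf = as.numeric(sum(tab >= 2L) >= 2L))
    })
    m <- stats["m", ]; g <- stats["g", ]; inf <- stats["inf", ] == 1
    M <- sum(m * w); G <- sum(g * w)
    ci <- if (L == 0) 1 else M / L
    ri <- if (G > M) (G - L) / (G - M) else NA_real_
    out <- list(ci = ci, ri = ri, M = M, G = G)
    if (!is.null(perPattern)) {
        Li <- sum(perPattern[inf] * w[inf])
        Mi <- sum(m[inf] * w[inf]); Gi <- sum(g[inf] * w[inf])
        out$ciInf <- if (Li == 0) 1 else Mi / Li
        out$riInf <- if (Gi > Mi) (Gi - Li) / (Gi - Mi) else NA_real_
    } else {
        out$ciInf <- NA_real_; out$riInf <- NA_real_
    }
    out
}

#' Consistency and retention indices of a tree on an alignment
#'
#' CI = M / L where M is the minimum conceivable length (sum over sites
#' of distinct non-missing states minus one) and L the observed Fitch
#' length; RI = (G - L) / (G - M) where G sums the per-site maximum
#' length (taxa minus largest state class). Both are also reported
#' restricted to parsimony-informative sites (at least two states each in
#' at least two taxa). Conventions: L = 0 gives CI = 1; G = M gives
#' RI = NA.
#'
#' @param aln named character vector (or DNAStringSet) of aligned
#'   sequences.
#' @param tree `ape::phylo` or Newick string.
#' @return list with ci, ri, ciInformative, riInformative, length, M, G.
#' @examples
#' aln <- c(s1 = "AA", s2 = "AC", s3 = "CA", s4 = "CC")
#' ciRi(aln, "((s1,s2),(s3,s4));")
#' @export
ciRi <- function(aln, tree) {
    code <- .alnCodes(aln)
    pats <- .alnPatterns(code)
    nb <- .phyloToNb(tree, pats$labels)
    perPattern <- .fitchCounts(nb, pats$pat, 1L)
    L <- sum(perPattern * pats$w)
    res <- .ciRiCore(pats, L, perPattern = perPattern)
    list(ci = res$ci, ri = res$ri,
         ciInformative = res$ciInf, riInformative = res$riInf,
         length = as.integer(L), M = res$M, G = res$G)
}

#' Bootstrap support for the edges of a parsimony tree
#'
#' Resamples alignment sites with replacement, reruns the TBR search on
#' each replicate (with a reduced restart count), and reports for each
#' internal edge of the best tree the percentage of replicate trees
#' containing the corresponding bipartition.
#'
#' @param aln named character vector (or DNAStringSet) of aligned
#'   sequences.
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed integer random seed.
#' @param restarts restarts for the initial full search (default 10).
#' @param repRestarts restarts per replicate search (default 1).
#' @param tree optional precomputed [ParsimonyTree-class] to annotate;
#'   when NULL the full search is run first.
#' @return a [ParsimonyTree-class] with the `support` slot filled
#'   (percent per internal node, root node first) and support stored as
#'   node labels of the topology.
#' @export
bootstrapSupport <- function(aln, reps = 100, seed = 1, restarts = 10,
                             repRestarts = 1, tree = NULL) {
    pdAssert(reps >= 1, "reps must be >= 1")
    code <- .alnCodes(aln)
    if (is.null(tree)) tree <- tbrSearch(aln, restarts = restarts, seed = seed)
    best <- treeTopology(tree)
    repTrees <- withStreamSeed(seed, "bootstrap", {
        lapply(seq_len(reps), function(i) {
            idx <- sample.int(ncol(code), replace = TRUE)
            pats <- .alnPatterns(code[, idx, drop = FALSE])
            res <- .tbrCore(pats, repRestarts, seed)
            ape::read.tree(text = .nbNewick(res$nb, pats$labels))
        })
    })
    cnt <- ape::prop.clades(best, repTrees, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    supp <- 100 * cnt / reps
    best$node.label <- format(round(supp, 1), trim = TRUE)
    new("ParsimonyTree", tree = best, score = tree@score,
        ci = tree@ci, ri = tree@ri,
        ciInformative = tree@ciInformative,
        riInformative = tree@riInformative,
        support = supp,
        metadata = c(tree@metadata,
                     list(bootstrapReps = reps,
                          bootstrapRestarts = repRestarts)))
}
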