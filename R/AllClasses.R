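#' MotifMatrix: a position frequency model of a transcription-factor site
#'
#' Stores per-position nucleotide counts for a binding-site model together
#' with the pseudocount and background distribution used to derive
#' probability and log2-odds matrices. The alphabet is fixed to A, C, G, T.
#'
#' @slot name motif name.
#' @slot counts 4 x W numeric matrix of non-negative counts, rows named
#'   A, C, G, T.
#' @slot pseudocount numeric added to every count before normalisation
#'   (default 0.5).
#' @slot background length-4 numeric background distribution (default
#'   uniform), named A, C, G, T.
#' @exportClass MotifMatrix
setClass("MotifMatrix",
    representation(
        name = "character",
        counts = "matrix",
        pseudocount = "numeric",
        background = "numeric"
    ),
    prototype(
        pseudocount = 0.5,
        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    )
)

setValidity("MotifMatrix", function(object) {
    msg <- character()
    cts <- object@counts
    if (!is.numeric(cts) || nrow(cts) != 4L)
        msg <- c(msg, "counts must be a numeric 4 x W matrix")
    if (ncol(cts) < 1L)
        msg <- c(msg, "motif width must be >= 1")
    if (any(cts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (!identical(rownames(cts), c("A", "C", "G", "T")))
        msg <- c(msg, "count rows must be named A, C, G, T")
    if (length(object@pseudocount) != 1L || object@pseudocount < 0)
        msg <- c(msg, "pseudocount must be a single non-negative number")
    bg <- object@background
    if (length(bg) != 4L || any(bg <= 0) || abs(sum(bg) - 1) > 1e-9)
        msg <- c(msg, "background must be 4 positive values summing to 1")
    # every probability column must sum to 1 after pseudocount
    pr <- sweep(cts + object@pseudocount, 2,
                colSums(cts + object@pseudocount), "/")
    if (any(abs(colSums(pr) - 1) > 1e-9))
        msg <- c(msg, "probability columns must sum to 1")
    if (length(msg)) msg else TRUE
})

#' Construct a MotifMatrix
#'
#' @param name motif name.
#' @param counts 4 x W non-negative count matrix; rows A, C, G, T (row
#'   names are added if absent).
#' @param pseudocount pseudocount added before normalisation.
#' @param background background nucleotide distribution (A, C, G, T).
#' @return A [MotifMatrix-class] object.
#' @examples
#' m <- MotifMatrix("toy", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), nrow = 4))
#' motifConsensus(m)
#' @export
MotifMatrix <- function(name, counts, pseudocount = 0.5,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) && nrow(counts) == 4L)
        rownames(counts) <- c("A", "C", "G", "T")
    new("MotifMatrix", name = name, counts = counts,
        pseudocount = pseudocount, background = background)
}

#' @describeIn MotifMatrix motif width (number of positions)
#' @param x,object a MotifMatrix.
#' @export
setMethod("ncol", "MotifMatrix", function(x) ncol(x@counts))

#' Motif width
#' @param x a [MotifMatrix-class].
#' @return integer number of positions.
#' @export
motifWidth <- function(x) ncol(x@counts)

#' Per-position probability matrix of a motif
#'
#' Counts plus pseudocount, normalised per column.
#' @param x a [MotifMatrix-class].
#' @return 4 x W probability matrix.
#' @export
motifProbabilities <- function(x) {
    cts <- x@counts + x@pseudocount
    sweep(cts, 2, colSums(cts), "/")
}

#' Per-position log2-odds matrix of a motif
#'
#' log2 of the probability matrix over the background distribution.
#' @param x a [MotifMatrix-class].
#' @return 4 x W log2-odds matrix.
#' @export
motifLogOdds <- function(x) {
    log2(motifProbabilities(x) / x@background)
}

#' Maximum achievable log2-odds score of a motif
#' @param x a [MotifMatrix-class].
#' @return numeric scalar.
#' @export
motifMaxScore <- function(x) sum(apply(motifLogOdds(x), 2, max))

#' Consensus string of a motif (highest-count base per column)
#' @param x a [MotifMatrix-class].
#' @return character consensus sequence.
#' @export
motifConsensus <- function(x) {
    paste(rownames(x@counts)[apply(x@counts, 2, which.max)], collapse = "")
}

#' @export
setMethod("show", "MotifMatrix", function(object) {
    cat("MotifMatrix '", object@name, "': width ", motifWidth(object),
        ", consensus ", motifConsensus(object),
        ", max log2-odds ", round(motifMaxScore(object), 2), "\n", sep = "")
})

#' ParsimonyTree: a maximum-parsimony tree with fit statistics
#'
#' Wraps an unrooted `ape::phylo` topology together with its parsimony
#' length, consistency/retention indices (all-sites and
#' parsimony-informative variants), optional per-edge bootstrap support,
#' and search metadata.
#'
#' @slot tree an unrooted binary `phylo`.
#' @slot score integer parsimony length (total site changes).
#' @slot ci,ri consistency and retention index over all sites (RI may be
#'   NA when undefined).
#' @slot ciInformative,riInformative the same indices restricted to
#'   parsimony-informative sites.
#' @slot support numeric bootstrap support (percent) per internal node, or
#'   length 0 when not computed.
#' @slot metadata list of search settings (restarts, seed, moves accepted,
#'   conventions).
#' @exportClass ParsimonyTree
setClass("ParsimonyTree",
    representation(
        tree = "ANY",
        score = "integer",
        ci = "numeric",
        ri = "numeric",
        ciInformative = "numeric",
        riInformative = "numeric",
        support = "numeric",
        metadata = "list"
    ),
    prototype(support = numeric(0), metadata = list())
)

setValidity("ParsimonyTree", function(object) {
    msg <- character()
    if (!inherits(object@tree, "phylo"))
        msg <- c(msg, "tree must be an ape phylo object")
    if (length(object@score) != 1L || object@score < 0)
        msg <- c(msg, "score must be a single non-negative integer")
    if (length(object@ci) == 1L && !is.na(object@ci) &&
        (object@ci < 0 || object@ci > 1))
        msg <- c(msg, "CI must lie in [0, 1]")
    if (length(object@ri) == 1L && !is.na(object@ri) &&
        (object@ri < 0 || object@ri > 1))
        msg <- c(msg, "RI must lie in [0, 1]")
    if (length(object@support) &&
        (any(object@support < 0 | object@support > 100, na.rm = TRUE)))
        msg <- c(msg, "bootstrap support must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ParsimonyTree", function(object) {
    cat("ParsimonyTree over", length(object@tree$tip.label), "taxa\n")
    cat("  length:", object@score,
        " CI:", signif(object@ci, 6), "(", signif(object@ciInformative, 6), ")",
        " RI:", signif(object@ri, 6), "(", signif(object@riInformative, 6), ")\n")
    if (length(object@support))
        cat("  bootstrap support on", length(object@support),
            "internal nodes\n")
})

#' Extract the phylo topology from a ParsimonyTree
#' @param x a [ParsimonyTree-class].
#' @return an `ape::phylo`.
#' @export
treeTopology <- function(x) x@tree

#' Parsimony length of a ParsimonyTree
#' @param x a [ParsimonyTree-class].
#' @return integer site-change count.
#' @export
treeScore <- function(x) x@score

#' Consistency / retention indices of a ParsimonyTree
#' @param x a [ParsimonyTree-class].
#' @return named numeric vector: ci, ri, ciInformative, riInformative.
#' @export
treeIndices <- function(x) {
    c(ci = x@ci, ri = x@ri,
      ciInformative = x@ciInformative, riInformative = x@riInformative)
}

#' Bootstrap support values of a ParsimonyTree
#' @param x a [ParsimonyTree-class].
#' @return numeric percent support per internal node (root first), or
#'   length-0 when not computed.
#' @export
treeSupport <- function(x) x@support

#' DatasetExpression: one expression dataset with a two-level condition
#'
#' A genes x samples expression matrix with its platform flag and
#' per-sample condition labels, as consumed by [perDatasetDE()].
#'
#' @slot id dataset identifier.
#' @slot exprs numeric genes x samples matrix; log2 scale for platform
#'   "log2-array", raw counts for platform "counts".
#' @slot condition factor with exactly two levels, reference (control)
#'   level first.
#' @slot platform "log2-array" or "counts".
#' @exportClass DatasetExpression
setClass("DatasetExpression",
    representation(
        id = "character",
        exprs = "matrix",
        condition = "factor",
        platform = "character"
    )
)

setValidity("DatasetExpression", function(object) {
    msg <- character()
    if (!object@platform %in% c("log2-array", "counts"))
        msg <- c(msg, "platform must be 'log2-array' or 'counts'")
    if (ncol(object@exprs) != length(object@condition))
        msg <- c(msg, "condition length must equal sample count")
    if (anyNA(object@condition))
        msg <- c(msg, "condition labels must not be missing")
    if (nlevels(object@condition) != 2L)
        msg <- c(msg, "condition must have exactly two levels")
    if (min(table(object@condition)) < 3L)
        msg <- c(msg, "each condition needs at least 3 samples")
    if (length(msg)) msg else TRUE
})

#' Construct a DatasetExpression
#' @param id dataset identifier.
#' @param exprs genes x samples numeric matrix.
#' @param condition two-level factor (or coercible), control level first.
#' @param platform "log2-array" (values already log2) or "counts".
#' @return a [DatasetExpression-class].
#' @export
DatasetExpression <- function(id, exprs, condition,
                              platform = c("log2-array", "counts")) {
    platform <- match.arg(platform)
    new("DatasetExpression", id = id, exprs = as.matrix(exprs),
        condition = as.factor(condition), platform = platform)
}

#' @export
setMethod("show", "DatasetExpression", function(object) {
    cat("DatasetExpression '", object@id, "' (", object@platform, "): ",
        nrow(object@exprs), " genes x ", ncol(object@exprs), " samples [",
        paste(table(object@condition), collapse = " vs "), "]\n", sep = "")
})
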