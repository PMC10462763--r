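#' @importFrom methods new validObject is
#' @importFrom stats p.adjust pt pnorm qnorm fisher.test phyper wilcox.test
#'   rnorm runif rbinom rnbinom rpois cor hclust cutree as.dist lm median
#'   setNames aggregate complete.cases sd var
#' @importFrom utils write.table read.table head tail packageVersion
NULL

# labelled error helper: all validation failures raise condition class
# "promdiverge_error" so callers (and the CLI) can distinguish them.
pdStop <- function(..., class = "promdiverge_error") {
    stop(structure(
        class = c(class, "error", "condition"),
        list(message = paste0(...), call = sys.call(-1))
    ))
}

pdAssert <- function(cond, ...) {
    if (!isTRUE(cond)) pdStop(...)
    invisible(TRUE)
}

#' Derive an independent random stream seed
#'
#' Hashes a global integer seed together with a stream name into a
#' deterministic 31-bit seed, so each generator draws from an independent
#' stream of one master seed.
#'
#' @param seed master integer seed.
#' @param stream character stream name.
#' @return a single integer in [0, 2^31 - 2].
#' @export
substreamSeed <- function(seed, stream) {
    pdAssert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "seed must be a single finite number")
    h <- as.double(seed %% 2147483647)
    for (ch in utf8ToInt(stream)) {
        h <- (h * 31 + ch) %% 2147483647
    }
    as.integer(h)
}

withStreamSeed <- function(seed, stream, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(substreamSeed(seed, stream))
    expr
}

# reverse complement of a plain character string (ACGTN)
revComp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' log2 counts-per-million transformation
#'
#' Library-size normalisation with a prior count, the transformation
#' applied to count matrices before linear modelling.
#'
#' @param counts genes x samples non-negative matrix.
#' @param prior prior count added after scaling (default 0.5).
#' @return genes x samples matrix of log2 CPM values.
#' @export
logCPM <- function(counts, prior = 0.5) {
    counts <- as.matrix(counts)
    libs <- colSums(counts)
    pdAssert(all(libs > 0), "all library sizes must be positive")
    log2(t(t(counts) / libs) * 1e6 + prior)
}

#' Benjamini-Hochberg adjustment with validation
#'
#' Step-up false-discovery-rate adjustment; adjusted values are returned
#' in the original input order and NA p-values propagate as NA.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of BH-adjusted values, q >= p elementwise.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    pdAssert(is.numeric(p), "p must be numeric")
    ok <- !is.na(p)
    pdAssert(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}
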