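#' Read motif matrices in JASPAR PFM format
#'
#' Parses the JASPAR position-frequency-matrix dialect: a header line
#' starting with `>` (identifier and optional name) followed by four count
#' rows labelled A, C, G, T, with counts optionally wrapped in square
#' brackets.
#'
#' @param path file to read, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @param pseudocount,background passed to [MotifMatrix()].
#' @return a named list of [MotifMatrix-class] objects.
#' @export
readJaspar <- function(path, text = NULL, pseudocount = 0.5,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
    lines <- if (!is.null(text)) text else readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    starts <- grep("^>", lines)
    pdAssert(length(starts) >= 1L, "no motif records found (no '>' header)")
    out <- list()
    bounds <- c(starts, length(lines) + 1L)
    for (i in seq_along(starts)) {
        hdr <- sub("^>\\s*", "", lines[starts[i]])
        toks <- strsplit(trimws(hdr), "\\s+")[[1]]
        name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
        body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
        pdAssert(length(body) == 4L,
                 "motif '", name, "': expected 4 count rows, got ",
                 length(body))
        rows <- matrix(NA_real_, nrow = 4L, ncol = 0L)
        lab <- character(4)
        vals <- vector("list", 4L)
        for (j in seq_len(4L)) {
            ln <- trimws(body[j])
            m <- regmatches(ln, regexec("^([ACGTacgt])\\s*\\[?([^]]*)\\]?\\s*$", ln))[[1]]
            if (length(m) < 3L)
                pdStop("motif '", name, "', line ", starts[i] + j,
                       ": unparseable count row")
            lab[j] <- toupper(m[2L])
            v <- suppressWarnings(as.numeric(strsplit(trimws(m[3L]), "\\s+")[[1]]))
            if (anyNA(v))
                pdStop("motif '", name, "', line ", starts[i] + j,
                       ": non-numeric counts")
            if (any(v < 0))
                pdStop("motif '", name, "', line ", starts[i] + j,
                       ": negative counts")
            vals[[j]] <- v
        }
        if (!setequal(lab, c("A", "C", "G", "T")))
            pdStop("motif '", name, "': row labels must be A, C, G, T (got ",
                   paste(lab, collapse = ","), ")")
        lens <- lengths(vals)
        if (length(unique(lens)) != 1L)
            pdStop("motif '", name, "': ragged count rows (widths ",
                   paste(lens, collapse = ","), ")")
        cts <- do.call(rbind, vals[match(c("A", "C", "G", "T"), lab)])
        rownames(cts) <- c("A", "C", "G", "T")
        out[[name]] <- MotifMatrix(name, cts, pseudocount = pseudocount,
                                   background = background)
    }
    out
}

#' Write motif matrices in JASPAR PFM format
#'
#' @param motifs a list of [MotifMatrix-class] objects.
#' @param path output file.
#' @return invisibly, the lines written.
#' @export
writeJaspar <- function(motifs, path) {
    if (is(motifs, "MotifMatrix")) motifs <- list(motifs)
    lines <- unlist(lapply(motifs, function(m) {
        c(paste0(">", m@name, " ", m@name),
          vapply(c("A", "C", "G", "T"), function(b) {
              paste0(b, " [ ", paste(format(m@counts[b, ], trim = TRUE),
                                     collapse = " "), " ]")
          }, character(1)))
    }))
    writeLines(lines, path)
    invisible(lines)
}

# encode an ACGTN string as integer codes 1..4, 0 for N/other
.encodeSeq <- function(seq) {
    codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
    v <- codes[strsplit(toupper(seq), "")[[1]]]
    v[is.na(v)] <- 0L
    unname(v)
}

# score every window start for one strand given a log-odds matrix;
# N (code 0) contributes 0 log-odds
.windowScores <- function(code, lo) {
    W <- ncol(lo)
    L <- length(code)
    n <- L - W + 1L
    if (n < 1L) return(numeric(0))
    lo0 <- rbind(0, lo)  # row 1 = N
    sc <- numeric(n)
    for (j in seq_len(W)) {
        sc <- sc + lo0[code[j:(j + n - 1L)] + 1L, j]
    }
    sc
}

#' Scan a sequence with a motif matrix
#'
#' Scores every window on both strands with the motif's log2-odds matrix
#' and returns the windows at or above the threshold. N bases score as
#' background (0 log-odds). Hits are reported with 0-based starts on the
#' forward sequence, sorted by start with "+" before "-".
#'
#' @param seq a character DNA string over A, C, G, T, N.
#' @param motif a [MotifMatrix-class].
#' @param threshold log2-odds score cutoff; default 80% of the motif's
#'   maximum achievable score.
#' @param seqId sequence identifier recorded in the output.
#' @return data.frame with columns seqId, start (0-based), strand, score,
#'   match (the scanned-strand substring).
#' @export
scanMotif <- function(seq, motif, threshold = NULL, seqId = "seq") {
    if (is.null(threshold)) threshold <- 0.8 * motifMaxScore(motif)
    pdAssert(is.finite(threshold), "threshold must be finite")
    seq <- toupper(as.character(seq))
    code <- .encodeSeq(seq)
    lo <- motifLogOdds(motif)
    W <- ncol(lo)
    if (length(code) < W)
        return(data.frame(seqId = character(), start = integer(),
                          strand = character(), score = numeric(),
                          match = character(), stringsAsFactors = FALSE))
    # minus strand: score of the reverse-complemented window equals the
    # forward-window score under the reverse-complemented matrix
    loRC <- lo[4:1, W:1, drop = FALSE]
    rownames(loRC) <- c("A", "C", "G", "T")
    fwd <- .windowScores(code, lo)
    rev <- .windowScores(code, loRC)
    fi <- which(fwd >= threshold); ri <- which(rev >= threshold)
    hits <- rbind(
        data.frame(start = fi - 1L, strand = rep("+", length(fi)),
                   score = fwd[fi], stringsAsFactors = FALSE),
        data.frame(start = ri - 1L, strand = rep("-", length(ri)),
                   score = rev[ri], stringsAsFactors = FALSE)
    )
    if (nrow(hits)) {
        hits <- hits[order(hits$start, hits$strand != "+"), , drop = FALSE]
        sub <- substring(seq, hits$start + 1L, hits$start + W)
        hits$match <- ifelse(hits$strand == "+", sub,
                             vapply(sub, revComp, character(1)))
    } else hits$match <- character(0)
    data.frame(seqId = rep(seqId, nrow(hits)), hits,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract a strand-aware promoter window around a TSS
#'
#' Coordinates are 0-based half-open. For a TSS at position t on the
#' "+" strand the window is `[t - upstream, t + downstream)`; on the "-"
#' strand it is `[t - downstream + 1, t + upstream + 1)` and the sequence
#' is reverse-complemented, so the returned string always reads upstream
#' to downstream. Windows running off the contig are clipped and flagged.
#'
#' @param gene gene identifier.
#' @param chrom contig name (must be present in `contigs`).
#' @param tss 0-based coordinate of the first transcribed base.
#' @param strand "+" or "-".
#' @param contigs named character vector (or DNAStringSet) of contig
#'   sequences.
#' @param upstream,downstream non-negative window extents in bp.
#' @return list with gene, chrom, start, end (0-based half-open genomic
#'   interval), strand, seq, clipped.
#' @export
promoterWindow <- function(gene, chrom, tss, strand, contigs,
                           upstream = 1000, downstream = 500) {
    pdAssert(upstream >= 0 && downstream >= 0,
             "upstream and downstream must be non-negative")
    pdAssert(strand %in% c("+", "-"), "strand must be '+' or '-'")
    pdAssert(chrom %in% names(contigs), "unknown contig: ", chrom)
    ctg <- as.character(contigs[[chrom]])
    L <- nchar(ctg)
    pdAssert(tss >= 0 && tss < L, "TSS outside contig bounds")
    if (strand == "+") {
        s0 <- tss - upstream; e0 <- tss + downstream
    } else {
        s0 <- tss - downstream + 1; e0 <- tss + upstream + 1
    }
    cs <- max(0, s0); ce <- min(L, e0)
    clipped <- (cs != s0) || (ce != e0)
    sq <- substring(ctg, cs + 1, ce)
    if (strand == "-") sq <- revComp(sq)
    list(gene = gene, chrom = chrom, start = cs, end = ce, strand = strand,
         seq = sq, clipped = clipped)
}

#' Differential motif enrichment between two promoter sets
#'
#' For each motif, counts the sequences in the primary and control sets
#' with at least one hit at the scan threshold and tests enrichment in the
#' primary set with a one-sided Fisher exact test; p-values are BH
#' adjusted across motifs. The enrichment ratio uses small pseudocounts to
#' stay finite: `((a + c) / (n1 + 2c)) / ((b + c) / (n2 + 2c))`.
#'
#' @param primary,control character vectors of promoter sequences (named
#'   or not); both must be non-empty.
#' @param motifs list of [MotifMatrix-class] objects.
#' @param threshold log2-odds cutoff; default 80% of each motif's maximum
#'   score. Either a single fraction-of-max when `relative = TRUE`
#'   (default) or an absolute score.
#' @param relative interpret `threshold` as a fraction of the motif's
#'   maximum score.
#' @param ratioPseudo pseudocount c in the enrichment ratio (default 0.1).
#' @param qCut significance cutoff on the BH q-value (default 0.05).
#' @return data.frame, one row per motif: motif, a, n1, b, n2, ratio, p,
#'   q, significant, note; ordered by q then p. Motifs wider than the
#'   shortest sequence get a note and NA statistics instead of an error.
#' @export
motifEnrichment <- function(primary, control, motifs, threshold = 0.8,
                            relative = TRUE, ratioPseudo = 0.1, qCut = 0.05) {
    pdAssert(length(primary) >= 1L && length(control) >= 1L,
             "both sequence sets must be non-empty")
    if (is(motifs, "MotifMatrix")) motifs <- list(motifs)
    primary <- vapply(primary, as.character, character(1))
    control <- vapply(control, as.character, character(1))
    n1 <- length(primary); n2 <- length(control)
    minLen <- min(nchar(c(primary, control)))
    rows <- lapply(motifs, function(m) {
        thr <- if (relative) threshold * motifMaxScore(m) else threshold
        if (motifWidth(m) > minLen) {
            return(data.frame(motif = m@name, a = NA_integer_, n1 = n1,
                              b = NA_integer_, n2 = n2, ratio = NA_real_,
                              p = NA_real_,
                              note = "motif wider than shortest sequence",
                              stringsAsFactors = FALSE))
        }
        hasHit <- function(s) nrow(scanMotif(s, m, threshold = thr)) > 0L
        a <- sum(vapply(primary, hasHit, logical(1)))
        b <- sum(vapply(control, hasHit, logical(1)))
        p <- fisher.test(matrix(c(a, n1 - a, b, n2 - b), nrow = 2),
                         alternative = "greater")$p.value
        ratio <- ((a + ratioPseudo) / (n1 + 2 * ratioPseudo)) /
                 ((b + ratioPseudo) / (n2 + 2 * ratioPseudo))
        data.frame(motif = m@name, a = a, n1 = n1, b = b, n2 = n2,
                   ratio = ratio, p = p, note = "", stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$q <- bhAdjust(res$p)
    res$significant <- !is.na(res$q) & res$q <= qCut
    res <- res[order(res$q, res$p), c("motif", "a", "n1", "b", "n2",
                                      "ratio", "p", "q", "significant",
                                      "note")]
    rownames(res) <- NULL
    res
}
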