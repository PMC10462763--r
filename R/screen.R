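# Multi-stage activation-biomarker screen: promoter occupancy by
# AP1-family binding intervals, meta-analytic upregulation, upregulation
# in every disease cohort, and cell-type selectivity.

#' AP1-family transcription factor labels
#'
#' The Jun and Fos family members whose binding clusters define promoter
#' occupancy in the default screen.
#' @export
AP1_FAMILY <- c("JUN", "JUNB", "JUND", "FOS", "FOSL1", "FOSL2")

#' Read a 4-column BED file of TF binding intervals
#'
#' BED conventions: 0-based half-open [start, end), fourth column = TF
#' label.
#'
#' @param path BED file.
#' @return data.frame: chrom, start, end, tf.
#' @export
readBindingBed <- function(path) {
    bed <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    pdAssert(ncol(bed) >= 4L, "BED file needs 4 columns (chrom start end tf)")
    bed <- bed[, 1:4]
    colnames(bed) <- c("chrom", "start", "end", "tf")
    pdAssert(all(bed$start < bed$end), "BED intervals need start < end")
    pdAssert(all(bed$start >= 0), "BED intervals need non-negative starts")
    bed
}

#' Map TF binding intervals to promoter windows
#'
#' Flags a gene when at least one interval carrying any of the requested
#' TF labels overlaps (by >= 1 bp) its strand-aware promoter window: for
#' a 0-based TSS t, `[t - upstream, t + downstream)` on "+" and
#' `[t - downstream + 1, t + upstream + 1)` on "-" (the
#' [promoterWindow()] convention). Windows are clamped at coordinate 0.
#'
#' @param intervals data.frame with chrom, start, end, tf (0-based
#'   half-open), e.g. from [readBindingBed()].
#' @param genes data.frame with gene, chrom, tss (0-based), strand.
#' @param upstream,downstream window extents in bp (defaults 2000 and
#'   1000).
#' @param tfFamily TF labels defining occupancy (default [AP1_FAMILY]);
#'   all requested labels must occur in the interval set's vocabulary
#'   union [AP1_FAMILY].
#' @return list: genes (character vector of flagged genes), support
#'   (data.frame gene x interval of supporting overlaps).
#' @export
mapBindingToGenes <- function(intervals, genes, upstream = 2000,
                              downstream = 1000, tfFamily = AP1_FAMILY) {
    pdAssert(all(c("chrom", "start", "end", "tf") %in% colnames(intervals)),
             "intervals need chrom, start, end, tf columns")
    pdAssert(all(c("gene", "chrom", "tss", "strand") %in% colnames(genes)),
             "genes need gene, chrom, tss, strand columns")
    pdAssert(!anyDuplicated(genes$gene), "gene ids must be unique")
    pdAssert(all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
    known <- union(unique(intervals$tf), AP1_FAMILY)
    bad <- setdiff(tfFamily, known)
    pdAssert(length(bad) == 0L, "unknown TF label(s): ",
             paste(bad, collapse = ", "))
    iv <- intervals[intervals$tf %in% tfFamily, , drop = FALSE]
    ws <- ifelse(genes$strand == "+", genes$tss - upstream,
                 genes$tss - downstream + 1)
    we <- ifelse(genes$strand == "+", genes$tss + downstream,
                 genes$tss + upstream + 1)
    ws <- pmax(ws, 0)
    if (nrow(iv) == 0L)
        return(list(genes = character(0),
                    support = data.frame(gene = character(0),
                                         chrom = character(0),
                                         start = integer(0), end = integer(0),
                                         tf = character(0))))
    # 0-based half-open -> 1-based closed for IRanges
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(ws + 1, we))
    ir <- GenomicRanges::GRanges(iv$chrom,
                                 IRanges::IRanges(iv$start + 1, iv$end))
    hits <- GenomicRanges::findOverlaps(gr, ir, minoverlap = 1L)
    gi <- S4Vectors::queryHits(hits); ii <- S4Vectors::subjectHits(hits)
    flagged <- sort(unique(genes$gene[gi]))
    support <- data.frame(gene = genes$gene[gi], chrom = iv$chrom[ii],
                          start = iv$start[ii], end = iv$end[ii],
                          tf = iv$tf[ii], stringsAsFactors = FALSE)
    list(genes = flagged, support = support)
}

#' Run the multi-stage biomarker screen
#'
#' Stage 1: genes with AP1-family promoter occupancy. Stage 2: stage-1
#' genes with pooled meta-analytic logFC > 0 and meta BH q <= `metaQ`.
#' Stage 3: stage-2 genes with logFC > 0 and BH q <= `cohortQ` in every
#' supplied cohort. Stage 4: stage-3 genes flagged cell-type selective.
#' Candidates are ranked by pooled meta effect (largest first).
#'
#' @param ap1Genes character vector of stage-1 genes (e.g.
#'   `mapBindingToGenes(...)$genes`).
#' @param meta meta-analysis table from [metaAnalysis()].
#' @param cohorts named list of per-cohort DE tables (columns gene,
#'   logFC, q), e.g. from [pseudobulkDE()] or [perDatasetDE()]; every
#'   cohort must share genes with stage 2 candidates' universe.
#' @param selective named logical vector (or character vector of
#'   selective genes) from [cellSpecificity()] runs.
#' @param metaQ,cohortQ significance cutoffs (defaults 0.05).
#' @return list of class-like structure: `table` (per-gene stage flags,
#'   candidate flag and rank), `stages` (named stage sizes), `candidates`
#'   (ranked character vector), `thresholds`.
#' @export
runScreen <- function(ap1Genes, meta, cohorts, selective,
                      metaQ = 0.05, cohortQ = 0.05) {
    pdAssert(is.list(cohorts) && length(cohorts) >= 1L,
             "at least one cohort is required")
    if (is.null(names(cohorts)))
        names(cohorts) <- paste0("cohort", seq_along(cohorts))
    if (is.character(selective))
        selective <- setNames(rep(TRUE, length(selective)), selective)
    universe <- sort(unique(c(ap1Genes, meta$gene)))
    stage1 <- intersect(universe, ap1Genes)
    mOK <- meta$gene[!is.na(meta$q) & meta$logFC > 0 & meta$q <= metaQ]
    stage2 <- intersect(stage1, mOK)
    stage3 <- stage2
    cohortFlags <- matrix(FALSE, nrow = length(universe),
                          ncol = length(cohorts),
                          dimnames = list(universe, names(cohorts)))
    for (nm in names(cohorts)) {
        co <- cohorts[[nm]]
        shared <- intersect(universe, co$gene)
        pdAssert(length(shared) > 0L,
                 "cohort '", nm, "' shares no genes with the screen")
        up <- co$gene[!is.na(co$q) & co$logFC > 0 & co$q <= cohortQ]
        cohortFlags[intersect(universe, up), nm] <- TRUE
        stage3 <- intersect(stage3, up)
    }
    sel <- names(selective)[as.logical(selective)]
    stage4 <- intersect(stage3, sel)
    rank0 <- setNames(rep(NA_integer_, length(universe)), universe)
    if (length(stage4)) {
        eff <- meta$logFC[match(stage4, meta$gene)]
        stage4 <- stage4[order(-eff)]
        rank0[stage4] <- seq_along(stage4)
    }
    tab <- data.frame(
        gene = universe,
        ap1_window = universe %in% stage1,
        meta_up = universe %in% mOK,
        stringsAsFactors = FALSE)
    for (nm in names(cohorts))
        tab[[paste0("up_in_", nm)]] <- cohortFlags[, nm]
    tab$cell_selective <- universe %in% sel
    tab$candidate <- universe %in% stage4
    tab$rank <- rank0[universe]
    tab$pooledLogFC <- meta$logFC[match(universe, meta$gene)]
    list(table = tab,
         stages = c(stage1 = length(stage1), stage2 = length(stage2),
                    stage3 = length(stage3), stage4 = length(stage4)),
         candidates = stage4,
         thresholds = list(metaQ = metaQ, cohortQ = cohortQ,
                           cohorts = names(cohorts)))
}

#' Write the screen report
#'
#' Emits the per-gene flag table as TSV and a JSON run manifest
#' (thresholds, stage counts, seed, package version) sufficient to re-run
#' the screen bit-identically from the same inputs.
#'
#' @param result list from [runScreen()].
#' @param dir output directory (created if needed).
#' @param seed the seed used for the run, recorded in the manifest.
#' @return invisibly, the paths written (tsv, manifest).
#' @export
screenReport <- function(result, dir, seed = NA) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(dir, "screen_results.tsv")
    write.table(result$table, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- list(
        stages = as.list(result$stages),
        candidates = result$candidates,
        thresholds = result$thresholds,
        seed = seed,
        tool = "promdiverge",
        version = as.character(packageVersion("promdiverge")))
    mp <- file.path(dir, "screen_manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
    invisible(c(tsv = tsv, manifest = mp))
}
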