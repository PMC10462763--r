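# Plain-text readers/writers for the pipeline's external formats:
# FASTA promoters, TSV expression + sample metadata, 4-column BED,
# MTX triplet single-cell matrices, and the YAML run configuration.

#' Write promoter sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read promoter sequences from FASTA
#' @param path FASTA file.
#' @return named character vector.
#' @export
readFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
}

#' Write an expression dataset as TSV pair
#'
#' Writes `<id>_expr.tsv` (genes x samples) and `<id>_samples.tsv`
#' (sample, condition) into `dir`.
#' @param ds a [DatasetExpression-class].
#' @param dir output directory.
#' @return invisibly, the two paths.
#' @export
writeExpressionDataset <- function(ds, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ep <- file.path(dir, paste0(ds@id, "_expr.tsv"))
    sp <- file.path(dir, paste0(ds@id, "_samples.tsv"))
    write.table(data.frame(gene = rownames(ds@exprs), ds@exprs,
                           check.names = FALSE),
                ep, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = colnames(ds@exprs),
                           condition = as.character(ds@condition),
                           platform = ds@platform),
                sp, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(expr = ep, samples = sp))
}

#' Read an expression dataset from a TSV pair
#' @param exprPath genes x samples TSV with a `gene` first column.
#' @param samplesPath TSV with sample, condition and optional platform
#'   columns.
#' @param id dataset id (default: the expression file stem).
#' @return a [DatasetExpression-class].
#' @export
readExpressionDataset <- function(exprPath, samplesPath, id = NULL) {
    ex <- read.table(exprPath, sep = "\t", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
    sm <- read.table(samplesPath, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    pdAssert("gene" %in% colnames(ex), exprPath, ": needs a 'gene' column")
    pdAssert(all(c("sample", "condition") %in% colnames(sm)),
             samplesPath, ": needs sample and condition columns")
    m <- as.matrix(ex[, -1, drop = FALSE])
    rownames(m) <- ex$gene
    pdAssert(all(sm$sample %in% colnames(m)),
             samplesPath, ": samples missing from the expression matrix")
    m <- m[, sm$sample, drop = FALSE]
    platform <- if ("platform" %in% colnames(sm)) sm$platform[1L]
                else "log2-array"
    if (is.null(id))
        id <- sub("_expr\\.tsv$", "", basename(exprPath))
    DatasetExpression(id, m, sm$condition, platform)
}

#' Write TF-binding intervals as 4-column BED
#' @param intervals data.frame chrom, start, end, tf (0-based half-open).
#' @param path output file.
#' @export
writeBed <- function(intervals, path) {
    write.table(intervals[, c("chrom", "start", "end", "tf")], path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write / read gene annotation TSV (gene, chrom, tss, strand)
#' @param genes annotation data.frame.
#' @param path TSV path.
#' @export
writeAnnotation <- function(genes, path) {
    write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(path) {
    g <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    pdAssert(all(c("gene", "chrom", "tss", "strand") %in% colnames(g)),
             path, ": needs gene, chrom, tss, strand columns")
    pdAssert(all(g$tss >= 0), path, ": negative TSS coordinates")
    g
}

#' Write a single-cell world as MTX triplet + TSVs
#'
#' Writes matrix.mtx, features.tsv, barcodes.tsv and metadata.tsv into
#' `dir`.
#' @param counts sparse gene x cell matrix.
#' @param cells per-cell metadata data.frame (first column `cell`).
#' @param dir output directory.
#' @export
writeScMtx <- function(counts, cells, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    write.table(cells, file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a single-cell world written by [writeScMtx()]
#' @param dir directory with matrix.mtx, features.tsv, barcodes.tsv,
#'   metadata.tsv.
#' @return list: counts (sparse), cells (data.frame).
#' @export
readScMtx <- function(dir) {
    counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    rownames(counts) <- readLines(file.path(dir, "features.tsv"))
    colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
    cells <- read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
    list(counts = methods::as(counts, "CsparseMatrix"), cells = cells)
}

#' Read a simulation configuration from YAML
#'
#' Unknown keys are rejected; the remaining keys override [simConfig()]
#' defaults.
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return a validated [simConfig()] object.
#' @export
readSimConfig <- function(path, seed = NULL) {
    y <- yaml::read_yaml(path)
    known <- names(formals(simConfig))
    bad <- setdiff(names(y), known)
    pdAssert(length(bad) == 0L, "unknown config key(s): ",
             paste(bad, collapse = ", "))
    if (!is.null(y$cellTypeProportions))
        y$cellTypeProportions <- unlist(y$cellTypeProportions)
    if (!is.null(y$activatedFraction))
        y$activatedFraction <- unlist(y$activatedFraction)
    if (!is.null(seed)) y$seed <- seed
    do.call(simConfig, y)
}

#' Write every simulated input of one configuration to a directory
#'
#' Generates the promoter, expression, single-cell and annotation worlds
#' from one configuration and writes them in their external formats
#' (FASTA, TSV, BED, MTX) together with the truth tables and a run
#' manifest.
#'
#' @param config a [simConfig()] object.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prom <- simulatePromoters(config)
    writeFasta(prom$sequences, file.path(dir, "promoters.fa"))
    write.table(prom$truth, file.path(dir, "promoters_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    expr <- simulateExpressionDatasets(config)
    for (ds in expr$datasets)
        writeExpressionDataset(ds, file.path(dir, "expression"))
    write.table(data.frame(gene = names(expr$truth$theta),
                           theta = expr$truth$theta),
                file.path(dir, "expression_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sc <- simulateScCounts(config)
    writeScMtx(sc$counts, sc$cells, file.path(dir, "sc"))
    writeLines(jsonlite::toJSON(sc$truth, pretty = TRUE),
               file.path(dir, "sc_truth.json"))
    ann <- simulateAnnotationIntervals(config)
    writeAnnotation(ann$genes, file.path(dir, "genes.tsv"))
    writeBed(ann$intervals, file.path(dir, "binding.bed"))
    write.table(ann$truth, file.path(dir, "occupancy_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(dir, subcommand = "simulate", seed = config$seed,
                  config = unclass(config)["seed" != names(config)],
                  inputs = character(0))
    invisible(dir)
}

#' Write a JSON run manifest
#'
#' Records the subcommand, seed, configuration, input-file digests
#' (md5), package version and timestamp beside the outputs, enabling a
#' bit-identical re-run of deterministic stages.
#'
#' @param dir output directory.
#' @param subcommand stage name.
#' @param seed integer seed used.
#' @param config list of settings.
#' @param inputs character vector of input file paths (digested).
#' @return invisibly, the manifest path.
#' @export
writeManifest <- function(dir, subcommand, seed, config = list(),
                          inputs = character(0)) {
    digests <- if (length(inputs))
        as.list(tools::md5sum(inputs)) else list()
    m <- list(subcommand = subcommand, seed = seed, config = config,
              inputDigests = digests,
              tool = "promdiverge",
              version = as.character(packageVersion("promdiverge")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    p <- file.path(dir, paste0(subcommand, "_manifest.json"))
    jsonlite::write_json(m, p, auto_unbox = TRUE, pretty = TRUE)
    invisible(p)
}
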