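# Synthetic-data generators. Every pipeline input can be generated with
# known ground truth: cross-species promoters with a clade-restricted
# motif gain, multi-dataset stimulated-vs-control expression matrices,
# cell-typed sparse single-cell counts with activated and homeostatic
# microglial subpopulations, gene annotation with TF-binding intervals,
# and an end-to-end screen world. One master integer seed drives
# everything; each generator hashes (seed, generator-name) into an
# independent stream, so outputs are byte-identical under a fixed seed.

# default 15-leaf mammal tree: a 3-leaf Muroidea clade (mouse, rat,
# chinese_hamster) among 12 other mammals; branch lengths in
# substitutions/site
.defaultSpeciesTree <- paste0(
    "(((((mouse:0.04,rat:0.04):0.05,chinese_hamster:0.08):0.12,",
    "(squirrel:0.12,guinea_pig:0.14):0.04):0.05,rabbit:0.16):0.03,",
    "((((human:0.02,chimp:0.02):0.03,macaque:0.05):0.04,marmoset:0.08):0.09,",
    "((pig:0.08,(cow:0.05,sheep:0.05):0.04):0.04,",
    "(dog:0.09,horse:0.08):0.03):0.05):0.04);")

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators.
#' Defaults define the package's reference study conditions; see the
#' methods vignette for the rationale behind each value.
#'
#' @param seed master integer seed; each generator derives an independent
#'   stream from it.
#' @param speciesTree Newick string with branch lengths
#'   (substitutions/site).
#' @param upstream,downstream promoter window extents around the TSS
#'   (defaults 1000 and 500 bp; promoter length is their sum).
#' @param substitutionRateScale multiplier on all branch lengths (>= 0).
#' @param plantedMotif name of the motif planted in the clade (one of the
#'   bundled motifs, default "AP1").
#' @param plantedClade leaf labels receiving the motif (default mouse,
#'   rat, chinese_hamster).
#' @param motifOffset planted motif start relative to the TSS (negative =
#'   upstream; default -400).
#' @param plantedMinScore minimum log2-odds score of the planted motif
#'   instance, as a fraction of the motif's maximum score (default 0.8,
#'   the default calling threshold): the planted site is a functional,
#'   detectable instance, drawn from the motif's probability matrix
#'   conditioned on clearing this score.
#' @param nDatasets,genesPerDataset,samplesPerGroup expression-world
#'   shape (defaults 10, 200, 4; at least 3 samples per group).
#' @param thetaMean true mean log2 stimulation effect of planted genes
#'   (default 1).
#' @param tau between-dataset SD of the planted effect (default 0.2).
#' @param sigma residual log2 SD (default 0.5).
#' @param nPlanted number of planted (non-null) genes (default 20).
#' @param countsFraction fraction of datasets emitted as RNA-seq-like
#'   counts rather than log2 arrays (default 0.2).
#' @param scSamples,scCellsPerSample single-cell world shape (defaults 8
#'   samples, 4 disease / 4 control, 200 cells each).
#' @param cellTypeProportions named proportions over cell types (must sum
#'   to 1).
#' @param nbDispersion negative-binomial size parameter (> 0; `Inf`
#'   selects the Poisson limit).
#' @param scLibrarySd log-normal SD of the per-cell library-size factor
#'   (default 0.3; 0 disables the technical size variation).
#' @param scGenes single-cell gene count (default 300).
#' @param activatedFraction named fractions of microglia in the activated
#'   subcluster per group.
#' @param activationFold,specificityRatio planted fold changes (defaults
#'   4 and 8).
#' @return a validated list of class "pdSimConfig".
#' @export
simConfig <- function(seed = 1,
                      speciesTree = .defaultSpeciesTree,
                      upstream = 1000, downstream = 500,
                      substitutionRateScale = 1,
                      plantedMotif = "AP1",
                      plantedClade = c("mouse", "rat", "chinese_hamster"),
                      motifOffset = -400,
                      plantedMinScore = 0.8,
                      nDatasets = 10, genesPerDataset = 200,
                      samplesPerGroup = 4,
                      thetaMean = 1, tau = 0.2, sigma = 0.5,
                      nPlanted = 20, countsFraction = 0.2,
                      scSamples = 8, scCellsPerSample = 200,
                      cellTypeProportions = c(microglia = 0.3,
                                              astrocyte = 0.2,
                                              neuron = 0.25,
                                              oligodendrocyte = 0.15,
                                              endothelial = 0.1),
                      nbDispersion = 2,
                      scLibrarySd = 0.3,
                      scGenes = 300,
                      activatedFraction = c(control = 0.15, disease = 0.5),
                      activationFold = 4, specificityRatio = 8) {
    cfg <- as.list(environment())
    for (nm in c("substitutionRateScale", "thetaMean", "tau", "sigma"))
        pdAssert(is.finite(cfg[[nm]]), nm, " must be finite")
    pdAssert(substitutionRateScale >= 0, "substitutionRateScale must be >= 0")
    pdAssert(samplesPerGroup >= 3, "samplesPerGroup must be >= 3")
    pdAssert(nDatasets >= 1, "nDatasets must be >= 1")
    pdAssert(sigma >= 0 && tau >= 0, "sigma and tau must be non-negative")
    pdAssert(abs(sum(cellTypeProportions) - 1) <= 1e-9,
             "cellTypeProportions must sum to 1")
    pdAssert(nbDispersion > 0, "nbDispersion must be positive")
    pdAssert(scSamples >= 4, "need >= 2 samples per group")
    class(cfg) <- "pdSimConfig"
    cfg
}

#' Bundled synthetic motif models
#'
#' Loads the synthetic AP1 / SPI1 / SP1 position frequency matrices
#' shipped with the package (constructed stand-ins of the corresponding
#' JASPAR-class motifs, not the database matrices).
#'
#' @return named list of [MotifMatrix-class] objects.
#' @export
bundledMotifs <- function() {
    readJaspar(system.file("extdata", "motifs_synthetic.jaspar",
                           package = "promdiverge"))
}

#' Generate cross-species promoters with a clade-restricted motif
#'
#' Evolves one promoter sequence per species along the configured tree
#' under an independent-sites, equal-rates (Jukes-Cantor-style)
#' substitution model without indels, then overwrites a motif instance
#' (sampled once from the motif's probability matrix) at the configured
#' TSS offset in every leaf of the planted clade. Because there are no
#' indels, the ungapped sequences are already aligned.
#'
#' @param config a [simConfig()] object.
#' @return list: sequences (named character vector, one per leaf, equal
#'   length), alignment (identical to sequences), tree (phylo), truth
#'   (data.frame: leaf, inClade, motifStart (0-based), motifEnd,
#'   instance), motif (the planted [MotifMatrix-class]).
#' @export
simulatePromoters <- function(config = simConfig()) {
    tree <- ape::read.tree(text = config$speciesTree)
    pdAssert(!is.null(tree), "species tree failed to parse")
    clade <- config$plantedClade
    bad <- setdiff(clade, tree$tip.label)
    pdAssert(length(bad) == 0L, "clade leaf absent from tree: ",
             paste(bad, collapse = ", "))
    motif <- bundledMotifs()[[config$plantedMotif]]
    pdAssert(!is.null(motif), "unknown planted motif: ", config$plantedMotif)
    L <- config$upstream + config$downstream
    W <- motifWidth(motif)
    start0 <- config$upstream + config$motifOffset
    pdAssert(start0 >= 0 && start0 + W <= L,
             "planted motif would overrun the promoter bounds")
    withStreamSeed(config$seed, "promoters", {
        bases <- c("A", "C", "G", "T")
        n <- length(tree$tip.label)
        root <- n + 1L
        seqs <- vector("list", n + tree$Nnode)
        seqs[[root]] <- sample.int(4L, L, replace = TRUE)
        # preorder edge traversal: parents are simulated before children
        eo <- rev(ape::postorder(tree))
        for (ei in eo) {
            a <- tree$edge[ei, 1L]; b <- tree$edge[ei, 2L]
            bl <- tree$edge.length[ei] * config$substitutionRateScale
            p <- 0.75 * (1 - exp(-4 / 3 * bl))
            s <- seqs[[a]]
            hit <- which(runif(L) < p)
            if (length(hit))
                s[hit] <- 1L + (s[hit] - 1L +
                                sample.int(3L, length(hit),
                                           replace = TRUE)) %% 4L
            seqs[[b]] <- s
        }
        # plant a functional (detectable) site: draw from the motif's
        # probability matrix conditioned on clearing the calling
        # threshold, so the planted truth is a site the scanner calls
        pr <- motifProbabilities(motif)
        lo <- motifLogOdds(motif)
        minScore <- config$plantedMinScore * motifMaxScore(motif)
        for (try in seq_len(1000L)) {
            ib <- apply(pr, 2, function(p) sample.int(4L, 1L, prob = p))
            if (sum(lo[cbind(ib, seq_len(W))]) >= minScore) break
        }
        if (sum(lo[cbind(ib, seq_len(W))]) < minScore)
            ib <- apply(lo, 2, which.max)
        inst <- bases[ib]
        out <- vapply(seq_len(n), function(i) {
            s <- bases[seqs[[i]]]
            if (tree$tip.label[i] %in% clade)
                s[(start0 + 1L):(start0 + W)] <- inst
            paste(s, collapse = "")
        }, character(1))
        names(out) <- tree$tip.label
        truth <- data.frame(
            leaf = tree$tip.label,
            inClade = tree$tip.label %in% clade,
            motifStart = ifelse(tree$tip.label %in% clade, start0, NA),
            motifEnd = ifelse(tree$tip.label %in% clade, start0 + W, NA),
            instance = ifelse(tree$tip.label %in% clade,
                              paste(inst, collapse = ""), NA),
            stringsAsFactors = FALSE)
        list(sequences = out, alignment = out, tree = tree, truth = truth,
             motif = motif)
    })
}

#' Generate multi-dataset stimulated-vs-control expression matrices
#'
#' Each dataset is a genes x samples matrix with a two-level condition
#' label. Planted genes carry a per-dataset effect
#' `delta_gd ~ Normal(thetaMean, tau^2)` added to the stimulated group on
#' the log2 scale; null genes have theta = 0, tau = 0. Baselines are
#' per-gene, per-dataset Normal(7, 1) log2 levels with Normal(0, sigma^2)
#' residual noise. A configurable fraction of datasets is emitted as
#' RNA-seq-like counts (2^log2 value, Poisson-sampled) flagged
#' platform = "counts"; the rest are log2 arrays.
#'
#' @param config a [simConfig()] object.
#' @param theta optional named vector of true effects per planted gene;
#'   default: the first `nPlanted` genes at `thetaMean`.
#' @return list: datasets (list of [DatasetExpression-class]), truth
#'   (list: theta named over all genes, delta genes x datasets matrix).
#' @export
simulateExpressionDatasets <- function(config = simConfig(), theta = NULL) {
    G <- config$genesPerDataset
    genes <- sprintf("g%04d", seq_len(G))
    th <- setNames(rep(0, G), genes)
    if (is.null(theta)) {
        nP <- min(config$nPlanted, G)
        th[seq_len(nP)] <- config$thetaMean
    } else {
        pdAssert(all(names(theta) %in% genes), "unknown planted gene names")
        th[names(theta)] <- theta
    }
    nD <- config$nDatasets
    nS <- config$samplesPerGroup
    nCounts <- round(config$countsFraction * nD)
    withStreamSeed(config$seed, "expression", {
        delta <- matrix(0, G, nD, dimnames = list(genes, NULL))
        planted <- th != 0
        datasets <- vector("list", nD)
        for (d in seq_len(nD)) {
            delta[planted, d] <- rnorm(sum(planted), th[planted], config$tau)
            base <- rnorm(G, 7, 1)
            x <- base + matrix(rnorm(G * 2 * nS, 0, config$sigma), G)
            x[, (nS + 1):(2 * nS)] <- x[, (nS + 1):(2 * nS)] + delta[, d]
            cond <- factor(rep(c("control", "stimulated"), each = nS),
                           levels = c("control", "stimulated"))
            colnames(x) <- paste0("s", seq_len(2 * nS))
            rownames(x) <- genes
            if (d <= nCounts) {
                cts <- matrix(rpois(length(x), lambda = 2^x), nrow = G,
                              dimnames = dimnames(x))
                datasets[[d]] <- DatasetExpression(sprintf("ds%02d", d), cts,
                                                   cond, "counts")
            } else {
                datasets[[d]] <- DatasetExpression(sprintf("ds%02d", d), x,
                                                   cond, "log2-array")
            }
        }
        colnames(delta) <- vapply(datasets, function(d) d@id, character(1))
        list(datasets = datasets, truth = list(theta = th, delta = delta))
    })
}

#' Generate cell-typed sparse single-cell counts
#'
#' Draws negative-binomial counts (Poisson in the `nbDispersion = Inf`
#' limit) with cell-type-specific means. Microglia are split into
#' homeostatic and activated subclusters (activated more frequent in the
#' disease group); planted activation genes are upregulated and the
#' planted homeostatic genes downregulated in the activated subcluster,
#' planted microglia-specific genes have mean expression
#' `specificityRatio`-fold above every other cell type, planted
#' pan-cellular genes are high everywhere, and a TSPO-like null gene is
#' flat across subclusters.
#'
#' @param config a [simConfig()] object.
#' @param genes optional gene names (default `scGenes` auto-named genes).
#' @return list: counts (sparse dgCMatrix gene x cell), cells
#'   (data.frame: cell, sample, group, cellType, subcluster), truth
#'   (lists of planted activation / homeostatic / specific / panCellular
#'   / null genes).
#' @export
simulateScCounts <- function(config = simConfig(), genes = NULL) {
    pdAssert(config$nbDispersion > 0, "dispersion must be positive")
    G <- config$scGenes
    if (is.null(genes)) genes <- sprintf("sc%04d", seq_len(G)) else
        G <- length(genes)
    types <- names(config$cellTypeProportions)
    pdAssert(length(types) >= 2L, "need at least 2 cell types")
    nMark <- max(3L, round(G * 0.03))
    activation <- genes[seq_len(nMark)]
    homeostatic <- genes[nMark + seq_len(nMark)]
    specific <- genes[2 * nMark + seq_len(nMark)]
    panCellular <- genes[3 * nMark + seq_len(nMark)]
    nullGene <- genes[4 * nMark + 1L]
    withStreamSeed(config$seed, "sccounts", {
        baseMu <- setNames(exp(rnorm(G, log(1.5), 0.8)), genes)
        # planted marker genes are robustly expressed (as real microglial
        # markers are), so pseudobulk tests have realistic counts to work
        # with
        marker <- c(activation, homeostatic, specific, panCellular, nullGene)
        baseMu[marker] <- pmax(baseMu[marker] * 4, 6)
        # per (cellType x subcluster) mean profiles
        mu <- sapply(types, function(ct) {
            m <- baseMu
            m[specific] <- if (ct == "microglia")
                m[specific] * config$specificityRatio else m[specific]
            m[panCellular] <- m[panCellular] * 4
            m
        })
        nS <- config$scSamples
        groups <- rep(c("control", "disease"), each = nS / 2)
        cellRows <- list(); cntCols <- list(); ci <- 0L
        for (s in seq_len(nS)) {
            grp <- groups[s]
            nC <- config$scCellsPerSample
            ct <- sample(types, nC, replace = TRUE,
                         prob = config$cellTypeProportions)
            sub <- rep("none", nC)
            mg <- ct == "microglia"
            sub[mg] <- ifelse(
                runif(sum(mg)) < config$activatedFraction[[grp]],
                "activated", "homeostatic")
            libF <- exp(rnorm(nC, 0, config$scLibrarySd))
            m <- matrix(0, G, nC)
            for (j in seq_len(nC)) {
                mj <- mu[, ct[j]]
                if (sub[j] == "activated") {
                    mj[activation] <- mj[activation] * config$activationFold
                    mj[homeostatic] <- mj[homeostatic] / config$activationFold
                }
                mj <- mj * libF[j]
                m[, j] <- if (is.infinite(config$nbDispersion))
                    rpois(G, mj) else
                    rnbinom(G, mu = mj, size = config$nbDispersion)
            }
            cellRows[[s]] <- data.frame(
                cell = sprintf("s%02d_c%04d", s, seq_len(nC)),
                sample = sprintf("s%02d", s), group = grp,
                cellType = ct, subcluster = sub, stringsAsFactors = FALSE)
            cntCols[[s]] <- m
        }
        counts <- do.call(cbind, cntCols)
        cells <- do.call(rbind, cellRows)
        dimnames(counts) <- list(genes, cells$cell)
        list(counts = Matrix::Matrix(counts, sparse = TRUE), cells = cells,
             truth = list(activation = activation,
                          homeostatic = homeostatic,
                          specific = specific,
                          panCellular = panCellular,
                          nullGene = nullGene))
    })
}

#' Generate gene annotation and TF-binding intervals
#'
#' Lays out genes along one synthetic contig, plants AP1-family binding
#' intervals inside the promoter window (2 kb upstream / 1 kb downstream
#' of the TSS, strand-aware) of a designated fraction of genes, adds
#' decoy AP1 intervals in intergenic space and background intervals for
#' other TFs, and records the realised occupancy truth by direct
#' interval arithmetic.
#'
#' @param config a [simConfig()] object.
#' @param nGenes number of genes (default 200).
#' @param occupiedFraction fraction of genes designated AP1-occupied
#'   (default 0.15).
#' @param upstream,downstream screen window extents (defaults 2000 and
#'   1000).
#' @return list: genes (data.frame gene, chrom, tss, strand), intervals
#'   (data.frame chrom, start, end, tf), truth (data.frame gene,
#'   occupied).
#' @export
simulateAnnotationIntervals <- function(config = simConfig(), nGenes = 200,
                                        occupiedFraction = 0.15,
                                        upstream = 2000, downstream = 1000) {
    pdAssert(nGenes >= 1, "nGenes must be >= 1")
    spacing <- 10000
    withStreamSeed(config$seed, "annotation", {
        tss <- 4000 + (seq_len(nGenes) - 1L) * spacing +
            sample.int(1000, nGenes, replace = TRUE)
        strand <- sample(c("+", "-"), nGenes, replace = TRUE)
        genes <- data.frame(gene = sprintf("g%04d", seq_len(nGenes)),
                            chrom = "chr1", tss = tss, strand = strand,
                            stringsAsFactors = FALSE)
        ws <- ifelse(strand == "+", tss - upstream, tss - downstream + 1)
        we <- ifelse(strand == "+", tss + downstream, tss + upstream + 1)
        occ <- sort(sample.int(nGenes, round(occupiedFraction * nGenes)))
        ivs <- lapply(occ, function(i) {
            w <- sample(80:300, 1L)
            s <- ws[i] + sample.int(max(we[i] - ws[i] - w, 1L), 1L) - 1L
            data.frame(chrom = "chr1", start = s, end = s + w,
                       tf = sample(AP1_FAMILY, 1L), stringsAsFactors = FALSE)
        })
        # decoy AP1 intervals in intergenic space + other-TF background
        gapStarts <- we + 500
        nDecoy <- round(nGenes * 0.2)
        di <- sample.int(nGenes, nDecoy, replace = TRUE)
        decoys <- data.frame(chrom = "chr1",
                             start = gapStarts[di] +
                                 sample.int(2000, nDecoy, replace = TRUE),
                             tf = sample(AP1_FAMILY, nDecoy, replace = TRUE),
                             stringsAsFactors = FALSE)
        decoys$end <- decoys$start + sample(80:300, nDecoy, replace = TRUE)
        other <- data.frame(chrom = "chr1",
                            start = sample.int(max(we) + 5000,
                                               nGenes, replace = TRUE),
                            tf = sample(c("SP1", "SPI1", "CTCF"), nGenes,
                                        replace = TRUE),
                            stringsAsFactors = FALSE)
        other$end <- other$start + sample(80:300, nGenes, replace = TRUE)
        intervals <- rbind(do.call(rbind, ivs),
                           decoys[c("chrom", "start", "end", "tf")],
                           other[c("chrom", "start", "end", "tf")])
        intervals <- intervals[order(intervals$start, intervals$end), ]
        rownames(intervals) <- NULL
        pdAssert(all(intervals$start >= 0), "negative interval coordinates")
        # realised truth by direct overlap arithmetic
        ap1 <- intervals[intervals$tf %in% AP1_FAMILY, , drop = FALSE]
        occupied <- vapply(seq_len(nGenes), function(i) {
            any(ap1$start < we[i] & ap1$end > max(ws[i], 0))
        }, logical(1))
        list(genes = genes, intervals = intervals,
             truth = data.frame(gene = genes$gene, occupied = occupied,
                                stringsAsFactors = FALSE))
    })
}

#' Generate block-structured expression for co-expression analysis
#'
#' Latent-factor blocks: genes in a block share one factor so that each
#' within-block pair has expected Pearson correlation `rho`;
#' between-block correlation is 0. Remaining genes are independent
#' noise.
#'
#' @param seed integer seed.
#' @param blockSizes integer vector of block sizes (default two blocks of
#'   40).
#' @param rho within-block correlation (default 0.9), recycled over
#'   blocks.
#' @param nNoise independent background genes (default 0).
#' @param nSamples samples (default 50).
#' @return list: expr (genes x samples matrix), blocks (named integer
#'   vector, 0 = noise gene).
#' @export
simulateModularExpression <- function(seed = 1, blockSizes = c(40, 40),
                                      rho = 0.9, nNoise = 0, nSamples = 50) {
    rho <- rep_len(rho, length(blockSizes))
    withStreamSeed(seed, "modular-expression", {
        rows <- list(); labs <- integer(0)
        for (b in seq_along(blockSizes)) {
            f <- rnorm(nSamples)
            m <- sqrt(rho[b]) * matrix(f, blockSizes[b], nSamples,
                                       byrow = TRUE) +
                 sqrt(1 - rho[b]) * matrix(rnorm(blockSizes[b] * nSamples),
                                           blockSizes[b])
            rows[[b]] <- m
            labs <- c(labs, rep(b, blockSizes[b]))
        }
        if (nNoise > 0) {
            rows[[length(rows) + 1L]] <- matrix(rnorm(nNoise * nSamples),
                                                nNoise)
            labs <- c(labs, rep(0L, nNoise))
        }
        expr <- do.call(rbind, rows)
        rownames(expr) <- sprintf("cg%04d", seq_len(nrow(expr)))
        colnames(expr) <- sprintf("s%03d", seq_len(nSamples))
        list(expr = expr, blocks = setNames(labs, rownames(expr)))
    })
}

#' Generate expression with a scale-free co-expression topology
#'
#' Single-factor model with heterogeneous loadings:
#' `x_i = a_i f + sqrt(1 - a_i^2) e_i` with `a_i = sqrt(U_i)`,
#' `U_i ~ Uniform(0, 1)`. Pairwise correlations are approximately
#' `a_i a_j`, so the signed-hybrid connectivity `k_i ~ a_i^beta` follows
#' a power law, yielding a scale-free degree distribution at moderate
#' powers.
#'
#' @param seed integer seed.
#' @param nGenes,nSamples matrix shape (defaults 300 and 100).
#' @return genes x samples matrix.
#' @export
simulateScaleFreeExpression <- function(seed = 1, nGenes = 300,
                                        nSamples = 100) {
    withStreamSeed(seed, "scalefree-expression", {
        a <- sqrt(runif(nGenes))
        f <- rnorm(nSamples)
        x <- a %o% f + sqrt(1 - a^2) * matrix(rnorm(nGenes * nSamples),
                                              nGenes)
        dimnames(x) <- list(sprintf("g%04d", seq_len(nGenes)),
                            sprintf("s%03d", seq_len(nSamples)))
        x
    })
}

#' Generate the end-to-end screen world
#'
#' Builds every input of [runScreen()] with known ground truth: gene
#' annotation with AP1-family binding intervals, a multi-dataset
#' in-vitro expression world for the meta-analysis, three disease
#' cohorts, and a single-cell matrix for cell-type specificity. Five
#' planted biomarkers satisfy all four stages; four decoy groups each
#' fail exactly one stage (no AP1 site; meta-null; up in only two of the
#' three cohorts; pan-cellular instead of microglia-selective). A
#' broader set of AP1-occupied, meta-up genes that are not upregulated
#' in the cohorts emulates the wider stage-2 pool.
#'
#' @param seed master integer seed.
#' @param nGenes total genes (default 2000).
#' @param nBiomarkers planted true biomarkers (default 5).
#' @param nPerDecoy decoys per failure mode (default 5).
#' @param nStage2Extra additional AP1 + meta-up genes failing the cohort
#'   stage (default 45).
#' @param nDatasets in-vitro datasets (default 10).
#' @param cohortSamples samples per group per cohort (default 6).
#' @param metaEffect,cohortEffect planted log2 effects (defaults 1.5
#'   and 3).
#' @return list: world inputs (annotation, intervals, datasets, cohorts,
#'   scCounts, scCells) and truth (roles per gene).
#' @export
simulateScreenWorld <- function(seed = 1, nGenes = 2000, nBiomarkers = 5,
                                nPerDecoy = 5, nStage2Extra = 45,
                                nDatasets = 10, cohortSamples = 6,
                                metaEffect = 1.5, cohortEffect = 3) {
    genes <- sprintf("g%04d", seq_len(nGenes))
    roles <- setNames(rep("background", nGenes), genes)
    idx <- 0L
    take <- function(n) {
        out <- genes[idx + seq_len(n)]
        idx <<- idx + n
        out
    }
    biomarkers <- take(nBiomarkers)
    decoyNoAp1 <- take(nPerDecoy)      # fails stage 1 only
    decoyMetaNull <- take(nPerDecoy)   # fails stage 2 only
    decoyCohort <- take(nPerDecoy)     # fails stage 3 only (2/3 cohorts)
    decoyPanCell <- take(nPerDecoy)    # fails stage 4 only
    stage2Extra <- take(nStage2Extra)  # AP1 + meta-up, not cohort-up
    roles[biomarkers] <- "biomarker"
    roles[decoyNoAp1] <- "decoy_no_ap1"
    roles[decoyMetaNull] <- "decoy_meta_null"
    roles[decoyCohort] <- "decoy_cohort"
    roles[decoyPanCell] <- "decoy_pan_cellular"
    roles[stage2Extra] <- "stage2_extra"

    # --- annotation + intervals: AP1 occupancy for everything except the
    # no-AP1 decoys plus a background fraction
    ann <- withStreamSeed(seed, "screen-annotation", {
        spacing <- 10000
        tss <- 4000 + (seq_len(nGenes) - 1L) * spacing +
            sample.int(1000, nGenes, replace = TRUE)
        strand <- sample(c("+", "-"), nGenes, replace = TRUE)
        ws <- ifelse(strand == "+", tss - 2000, tss - 1000 + 1)
        we <- ifelse(strand == "+", tss + 1000, tss + 2000 + 1)
        mustOcc <- c(biomarkers, decoyMetaNull, decoyCohort, decoyPanCell,
                     stage2Extra)
        bgOcc <- sample(genes[roles == "background"],
                        round(0.1 * sum(roles == "background")))
        occSet <- match(c(mustOcc, bgOcc), genes)
        ivs <- lapply(occSet, function(i) {
            w <- sample(80:300, 1L)
            s <- ws[i] + sample.int(max(we[i] - ws[i] - w, 1L), 1L) - 1L
            data.frame(chrom = "chr1", start = s, end = s + w,
                       tf = sample(AP1_FAMILY, 1L), stringsAsFactors = FALSE)
        })
        list(genes = data.frame(gene = genes, chrom = "chr1", tss = tss,
                                strand = strand, stringsAsFactors = FALSE),
             intervals = do.call(rbind, ivs))
    })

    # --- in-vitro meta world: biomarkers, cohort/pan-cellular/no-AP1
    # decoys and stage-2 extras are meta-up; meta-null decoys are null
    metaUp <- c(biomarkers, decoyNoAp1, decoyCohort, decoyPanCell,
                stage2Extra)
    theta <- setNames(rep(metaEffect, length(metaUp)), metaUp)
    cfg <- simConfig(seed = substreamSeed(seed, "screen-expression"),
                     nDatasets = nDatasets, genesPerDataset = nGenes,
                     samplesPerGroup = 4)
    exprWorld <- simulateExpressionDatasets(cfg, theta = theta)

    # --- three disease cohorts; cohort decoys are up in cohorts 1-2 only
    cohorts <- withStreamSeed(seed, "screen-cohorts", {
        lapply(1:3, function(co) {
            up <- c(biomarkers, decoyNoAp1, decoyPanCell,
                    if (co < 3) decoyCohort)
            eff <- setNames(rep(0, nGenes), genes)
            eff[up] <- cohortEffect
            base <- rnorm(nGenes, 7, 1)
            nS <- cohortSamples
            x <- base + matrix(rnorm(nGenes * 2 * nS, 0, 0.5), nGenes)
            x[, (nS + 1):(2 * nS)] <- x[, (nS + 1):(2 * nS)] + eff
            rownames(x) <- genes
            colnames(x) <- paste0("c", seq_len(2 * nS))
            DatasetExpression(paste0("cohort", co), x,
                              factor(rep(c("control", "disease"), each = nS),
                                     levels = c("control", "disease")),
                              "log2-array")
        })
    })
    names(cohorts) <- paste0("cohort", 1:3)

    # --- single-cell world for specificity: role genes + background
    scGenes <- c(biomarkers, decoyNoAp1, decoyMetaNull, decoyCohort,
                 decoyPanCell,
                 withStreamSeed(seed, "screen-sc-genes", {
                     bg <- genes[roles == "background"]
                     sample(bg, min(400L, length(bg)))
                 }))
    # 250 cells/sample keeps even the rarest cell type (10%) safely
    # above the pseudobulk cell floor in every sample
    scCfg <- simConfig(seed = substreamSeed(seed, "screen-sc"),
                       scSamples = 8, scCellsPerSample = 250,
                       scGenes = length(scGenes))
    sc <- withStreamSeed(seed, "screen-sc-build", {
        types <- names(scCfg$cellTypeProportions)
        mgSelective <- c(biomarkers, decoyNoAp1, decoyMetaNull, decoyCohort)
        baseMu <- setNames(exp(rnorm(length(scGenes), log(2), 0.6)), scGenes)
        mu <- sapply(types, function(ct) {
            m <- baseMu
            if (ct == "microglia")
                m[mgSelective] <- m[mgSelective] * scCfg$specificityRatio
            m[decoyPanCell] <- m[decoyPanCell] * 4
            m
        })
        nS <- scCfg$scSamples
        cellRows <- list(); cols <- list()
        for (s in seq_len(nS)) {
            nC <- scCfg$scCellsPerSample
            ct <- sample(types, nC, replace = TRUE,
                         prob = scCfg$cellTypeProportions)
            libF <- exp(rnorm(nC, 0, scCfg$scLibrarySd))
            m <- matrix(rnbinom(length(scGenes) * nC,
                                mu = mu[, ct] %*% diag(libF, nC),
                                size = scCfg$nbDispersion),
                        length(scGenes), nC)
            cellRows[[s]] <- data.frame(
                cell = sprintf("s%02d_c%04d", s, seq_len(nC)),
                sample = sprintf("s%02d", s),
                cellType = ct, stringsAsFactors = FALSE)
            cols[[s]] <- m
        }
        counts <- do.call(cbind, cols)
        cells <- do.call(rbind, cellRows)
        dimnames(counts) <- list(scGenes, cells$cell)
        list(counts = Matrix::Matrix(counts, sparse = TRUE), cells = cells)
    })

    list(annotation = ann$genes, intervals = ann$intervals,
         datasets = exprWorld$datasets, cohorts = cohorts,
         scCounts = sc$counts, scCells = sc$cells,
         truth = list(roles = roles, biomarkers = biomarkers,
                      decoys = list(no_ap1 = decoyNoAp1,
                                    meta_null = decoyMetaNull,
                                    cohort = decoyCohort,
                                    pan_cellular = decoyPanCell),
                      stage2Extra = stage2Extra,
                      theta = exprWorld$truth$theta))
}

#' Run the full screen pipeline on a simulated world
#'
#' Per-dataset DE and meta-analysis on the in-vitro world, per-cohort DE,
#' AP1 window mapping, cell-type specificity for the stage-3 survivors,
#' and the four-stage screen.
#'
#' @param world list from [simulateScreenWorld()].
#' @param metaQ,cohortQ,foldCut screen thresholds (defaults 0.05, 0.05,
#'   4).
#' @return the [runScreen()] result, plus `meta` and `specificity`
#'   attached.
#' @export
runScreenPipeline <- function(world, metaQ = 0.05, cohortQ = 0.05,
                              foldCut = 4) {
    effects <- lapply(world$datasets, perDatasetDE)
    meta <- metaAnalysis(effects)
    cohortDE <- lapply(world$cohorts, perDatasetDE)
    ap1 <- mapBindingToGenes(world$intervals, world$annotation)
    # provisional screen to find stage-3 survivors, then test specificity
    pre <- runScreen(ap1$genes, meta, cohortDE,
                     selective = character(0),
                     metaQ = metaQ, cohortQ = cohortQ)
    stage3 <- pre$table$gene[pre$table$ap1_window & pre$table$meta_up &
        rowSums(!as.matrix(pre$table[grep("^up_in_", names(pre$table))])) == 0]
    stage3 <- intersect(stage3, rownames(world$scCounts))
    spec <- lapply(stage3, function(g) {
        cellSpecificity(world$scCounts, world$scCells, g, "microglia",
                        foldCut = foldCut)
    })
    names(spec) <- stage3
    selective <- vapply(spec, `[[`, logical(1), "selective")
    res <- runScreen(ap1$genes, meta, cohortDE, selective = selective,
                     metaQ = metaQ, cohortQ = cohortQ)
    res$meta <- meta
    res$specificity <- spec
    res
}
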