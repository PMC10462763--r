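---
title: "Methods: promoter motif divergence and activation-marker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter motif divergence and activation-marker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdiverge)
```

# Scope and scientific setting

`promdiverge` implements the computational skeleton of a comparative
regulatory-genomics study: a transcription factor binding site (an AP1
site, bound by Jun/Fos dimers) is present in the core promoter of a gene
in some species and absent in others, and that presence is hypothesised
to explain why the gene is stimulus-inducible in myeloid cells of those
species only. The motivating case is the TSPO gene, whose inducibility
is restricted to a subset of Muroidea rodents (mouse, rat, Chinese
hamster), with downstream consequences for interpreting TSPO-PET imaging
of human neuroinflammation; the same machinery then drives a screen for
alternative activation markers (genes such as LCP2 and TFEC) that carry
the AP1 site and behave consistently across in-vitro stimulation,
disease cohorts, and cell-type specificity filters.

The package provides six analysis stages plus a synthetic-data module
that generates every input with known ground truth, so the whole
pipeline is testable offline:

1. **Motif analysis** — JASPAR PFM parsing, strand-aware promoter
   windows, log2-odds scanning, and set-vs-set differential enrichment
   (one-sided Fisher exact test, Benjamini–Hochberg correction).
2. **Parsimony phylogenetics** — Fitch counting, heuristic
   tree-bisection-reconnection (TBR) search, bootstrap support, and
   consistency/retention indices on promoter alignments.
3. **Expression meta-analysis** — per-dataset OLS differential
   expression pooled with the DerSimonian–Laird random-effects
   estimator.
4. **Single-cell stage** — AUCell-style per-cell gene-set scores,
   subcluster labelling, pseudobulking, pseudobulk DE, and cell-type
   specificity tests.
5. **Co-expression** — signed-hybrid adjacency, topological overlap,
   module detection, and cross-set module overlap.
6. **Biomarker screen** — the four-stage intersection of AP1 promoter
   occupancy, meta-analytic upregulation, per-cohort upregulation, and
   microglial selectivity.

# Models and procedures

## Motif scanning and enrichment

A motif is a 4 × W count matrix; probabilities add a pseudocount (0.5)
per cell and log2-odds are taken against a uniform background. A window
scores the sum of per-position log-odds; N scores zero. Both strands are
scanned; the default calling threshold is 80% of the motif's maximum
achievable score. The threshold is deliberately conservative: it calls
near-consensus sites, which is the regime in which presence/absence
comparisons across species are meaningful. Enrichment between a primary
and a control sequence set counts sequences with at least one hit and
applies a one-sided Fisher exact test, BH-adjusted across motifs. The
reported enrichment ratio uses pseudocounts of 0.1 to stay finite at
zero counts. The SEA (MEME-suite) E-value machinery is not reproduced;
the enrichment statistics here are the Fisher/BH pair, with the
significance gate expressed on the q-value (default 0.05).

Promoter windows are 0-based half-open. For a TSS at position $t$:
`[t - upstream, t + downstream)` on the plus strand and
`[t - downstream + 1, t + upstream + 1)` on the minus strand, with the
returned sequence always reading upstream→downstream. Two window sizes
recur: 1000 bp up / 500 bp down for cross-species divergence analysis,
and 2 kb up / 1 kb down for the occupancy screen.

## Maximum parsimony

Alignments are compressed to unique site patterns with weights; Fitch
counting works on bit-encoded states, with gaps and N treated as missing
data (any state, zero cost) — flagged in search metadata since tools
differ here. The search runs greedy random-addition starting trees
followed by first-improvement hill climbing over the full TBR
neighbourhood (bisection at every edge, exhaustive reconnection over
edge pairs, degree-2 suppression). Ties among equally short trees are
broken by the lexicographically smallest canonical Newick (rooted at the
alphabetically first taxon, children sorted), so results are
reproducible and invariant to taxon input order. Bootstrap support
resamples sites with replacement, reruns the search with a reduced
restart count, and reports bipartition frequencies on the best tree.

Indices: with $M = \sum_s (k_s - 1)$ (minimum conceivable length),
$L$ the observed Fitch length and $G = \sum_s (n_s - \max \text{class}_s)$,
the consistency index is $CI = M/L$ and the retention index
$RI = (G - L)/(G - M)$. Both are also reported restricted to
parsimony-informative sites (two states each in two or more taxa),
matching the parenthetical variants that tree-building software prints.
Conventions: $L = 0 \Rightarrow CI = 1$; $G = M \Rightarrow RI$ = NA.
The published tree statistics for the real 34-species promoter set
(length 4279 etc.) depend on externally downloaded promoters and a
T-Coffee alignment and are therefore out of scope here; alignments are
consumed, never computed.

## Random-effects meta-analysis

Per dataset, log2 expression (arrays) or log2 CPM with prior count 0.5
(counts) is modelled per gene by OLS on the two-level condition; the
condition coefficient is the log fold change with its t-based p-value.
The cross-dataset pool is DerSimonian–Laird: $w_i = 1/SE_i^2$,
$Q = \sum w_i (y_i - \bar y)^2$,
$\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}$,
random-effects weights $1/(SE_i^2 + \tau^2)$, a 1.96 multiplier for the
95% CI, $I^2 = \max\{0, (Q - (k-1))/Q\}$, and a normal-approximation
p-value, BH-adjusted across genes.

The moderated-variance machinery of limma/DESeq2 is intentionally
replaced by plain OLS, which keeps the estimator transparent but has a
known cost: with 5 samples per group the per-dataset SEs carry only 8
degrees of freedom, and inverse-variance weighting with such noisy SEs
is anticonservative — the true level of the nominal 5% meta test is
about 7% at $k = 10$ datasets (and Knapp–Hartung does not remove this
particular inflation, which enters through the weights rather than the
reference distribution). The acceptance script reports the measured
null rate (`meta_null_type1_rate`) so this calibration property is
checked rather than assumed. Effect estimates themselves are unbiased;
parameter recovery of a planted effect is accurate to well under 0.1
log2 units under the default conditions.

## Single-cell stage

AUCell-style scores rank a cell's genes by decreasing count (ties broken
by a seeded, recorded permutation) and integrate the recovery curve of
gene-set members over the top 5% of ranks, normalised by the maximum
achievable area; scores are rank-based and hence invariant to monotone
transformations of a cell's counts. Subclusters are labelled with the
gene set whose scores dominate: highest median, beating every other set
by a two-sided rank-sum test at BH q ≤ 0.05, otherwise "ambiguous".

Pseudobulking sums counts over (sample, cell type) — exactly, with
columns aggregating fewer than 10 cells dropped and logged; the floor is
a package default, chosen because sums over very few nuclei are
dominated by single-cell noise. Pseudobulk DE reuses the OLS model on
log2 CPM. Cell-type specificity compares the target type against every
other type by the per-sample paired log2 CPM ratio with a two-sided
signed-rank test; "selective" requires a ≥ 4-fold mean ratio against
every other type at BH q ≤ 0.05. Note the discreteness constraint of
the exact signed-rank test: with fewer than 6 paired samples the
two-sided p cannot reach 0.05, so specificity calls need at least 6
samples contributing both cell types.

## Co-expression

The network is signed-hybrid: $a_{ij} = \mathrm{cor}(i,j)^\beta$ for
positive Pearson correlations and 0 otherwise. The soft threshold
$\beta$ is the smallest power in 1–20 whose scale-free topology fit
reaches $R^2 \ge 0.85$, where the fit regresses log10 frequency on
log10 connectivity over 10 equal-width bins; a power only qualifies with
a negative slope (a decaying degree distribution), matching the
established convention. "Degree of independence" is read as this fit
statistic. Topological overlap is
$TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
with unit diagonal. Modules come from average-linkage clustering of
$1 - TOM$ with a static cut at height 0.95 and a minimum module size of
30; the dynamic hybrid tree-cut variant is replaced by this static cut,
which preserves the testable content (planted-partition recovery) with
a fully specified algorithm. Genes are pre-filtered by the
1-count-in-at-least-half-the-samples rule. Module overlap reports the
intersection, a one-sided hypergeometric p, and a seeded size-matched
random-module baseline.

## The screen

Stage 1 flags genes whose 2 kb/1 kb strand-aware TSS window overlaps
(≥ 1 bp) any interval labelled with an AP1-family TF
(JUN/JUNB/JUND/FOS/FOSL1/FOSL2). Stage 2 keeps stage-1 genes with
pooled meta logFC > 0 at meta BH q ≤ 0.05 — the paper states no numeric
threshold for "upregulated", so this operationalisation is explicit and
configurable. Stage 3 requires logFC > 0 and q ≤ 0.05 in *every*
supplied cohort; stage 4 requires cell-type selectivity. Candidates are
ranked by pooled effect. Every run writes a TSV of per-gene flags and a
JSON manifest (thresholds, input digests, seed) sufficient for a
bit-identical re-run. The published screen outputs (96 genes;
HK2/LCP2/TFEC; LCP2/TFEC after the specificity filter) require ENCODE
TF-cluster downloads and specific public cohorts, so they are structure,
not assertions, here: the synthetic world instead plants known
biomarkers and single-stage-failing decoys and requires exact recovery.

# The synthetic world

All generators hash one master seed with the generator name into
independent streams, so every output is byte-identical under a fixed
seed and no generator perturbs another's draws.

**Promoters.** A 15-leaf mammal tree (three Muroidea species — mouse,
rat, chinese hamster — among 12 other mammals, branch lengths in
substitutions/site on the order of 0.02–0.16) evolves a 1500 bp promoter
(1000 up / 500 down) under an independent-sites equal-rates
(Jukes–Cantor) model without indels, so the leaf sequences are already
aligned. A single AP1 instance is then overwritten at TSS offset −400 in
every clade leaf. The instance is drawn from the motif's probability
matrix *conditioned on scoring at least the calling threshold* (80% of
max): an unconditional PFM draw scores only ~65–75% of the maximum in
expectation, i.e. it frequently produces a "site" that neither this
scanner nor any conservative caller would report — a planted truth
should be a functional, detectable site. The bundled AP1/SPI1/SP1
matrices are synthetic constructions of the corresponding consensus
classes (TGACTCA core, GGAA core, GC-box), not copies of database
matrices.

**Expression.** Ten datasets, 4 samples per group by default (the
study-inclusion rule is ≥ 3), per-gene per-dataset baselines
N(7, 1) on the log2 scale, residual SD σ = 0.5, planted genes shifted in
the stimulated group by δ ~ N(θ, τ²) with θ = 1 and τ = 0.2. A fifth of
the datasets are emitted as RNA-seq-like Poisson counts (flagged
`counts`) to mirror mixed platforms; the rest are log2 arrays.

**Single cells.** Five cell types (microglia 30%, astrocyte 20%, neuron
25%, oligodendrocyte 15%, endothelial 10%), 8 samples (4 disease / 4
control), negative-binomial counts (size 2; `Inf` gives the Poisson
limit) with a log-normal per-cell library factor (SD 0.3, settable to
0). Microglia split into homeostatic and activated subclusters
(activated fraction 15% in controls, 50% in disease). Planted gene
groups: activation markers (×4 in activated cells), homeostatic markers
(÷4), microglia-specific genes (×8 over every other type), pan-cellular
genes, and one flat "TSPO-like" null gene. Planted markers are given
robust baseline expression, as real marker genes have; very low-count
genes would carry no pseudobulk information.

**Screen world.** 2000 genes; five planted biomarkers pass all four
stages; four decoy groups of five fail exactly one stage each (no AP1
interval; meta-null; up in only two of three cohorts; pan-cellular);
45 further AP1+meta-up genes emulate the broader stage-2 pool (so the
default stage-2 size is ~60 against the screen's 2000-gene universe).
Cohorts are three bulk-style disease datasets with 6 samples per group
and planted log2 effects of 3 for cohort-positive genes — effect sizes
in the range seen for disease-associated-microglia markers, and chosen,
as all generator defaults are, for adequate test power rather than as
estimates of any real dataset. The specificity world uses 250 cells per
sample so the rarest cell type stays above the pseudobulk floor in
every sample (see the signed-rank discreteness constraint above).

**What the generators do not emulate:** read-level noise, batch effects
across cohorts, doublets and ambient RNA, indels and alignment error,
correlated gene-gene structure within the meta world. Passing tests
demonstrate that the algorithms recover what was planted under these
idealised conditions; they do not certify performance on real data with
those additional artefacts.

# Numerical choices and degenerate inputs

- SEs in OLS DE are floored at 1e-8 so noise-free data remain finite;
  genes with under two usable samples in a condition return NA with a
  reason code.
- `dlMeta` with one study returns that study (τ² = 0, Q = 0); I² is 0
  when Q = 0.
- Fitch counting treats an all-missing site as zero-cost; `ciRi` reports
  RI = NA when G = M (no site can be homoplastic).
- Tree-search tie-breaks, AUCell rank ties and all Monte-Carlo baselines
  are seeded and recorded in metadata/manifests.
- Scanning a sequence shorter than the motif returns an empty hit table;
  enrichment records a note for motifs wider than the shortest sequence
  instead of failing.
- BH adjustment propagates NAs and validates the [0, 1] range.

# Problem sizes used in the checks

The test-suite and acceptance script sizes are chosen so each check is
statistically meaningful at desk scale: exhaustive-search comparisons at
≤ 7 taxa × 50 sites (945 topologies), brute-force Fitch at 6 taxa,
100 random 2×2 tables for the Fisher oracle, 50-seed meta recovery, 500
null genes for calibration, 20-seed Monte-Carlo for clade recovery,
enrichment ranking, the single-cell activation pattern, and the
end-to-end screen on the default 2000-gene world.

# Known limitations

- The nominal 5% random-effects meta test runs at ~7% true level under
  small per-dataset sample sizes, as discussed above; with moderated or
  known variances the inflation disappears. Directions and effect
  magnitudes are unaffected.
- The heuristic TBR search guarantees no global optimum; it matches
  exhaustive search on every tested small instance and is restart-robust
  at the scales used here, but large promiscuous alignments may need
  more restarts.
- The static TOM tree cut can split very close modules that the dynamic
  hybrid cutter would merge; at the planted block strengths tested the
  two coincide.
- Cell-type specificity inherits the exact signed-rank discreteness: at
  fewer than six paired samples no gene can be called selective.
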