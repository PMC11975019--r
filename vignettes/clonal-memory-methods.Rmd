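---
title: "Methods: detecting clonally heritable epigenetic states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting clonally heritable epigenetic states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalmem)
```

# The problem

Inflammatory injury can leave a lasting mark on tissue stem cells: after
colitis resolves, a subset of intestinal stem cells retains elevated
accessibility at AP-1 (Fos/Jun) transcription-factor motifs, and this
state is transmitted through cell divisions. Demonstrating that an
epigenetic state is *clonally heritable* — rather than a transient
response redrawn in every cell — requires reading three things from the
same cells: a lineage barcode (who is related to whom), chromatin state
(motif-level accessibility), and transcriptome (gene programs).

`clonalmem` implements the computational chain for this kind of
experiment: expressed-barcode clone calling, background-corrected
per-cell scoring of motif families and gene programs, a permutation test
for clonal heritability of those scores, neighbourhood condition
enrichment, transcription-factor co-binding analysis from footprint
changes, and spatial tumor segmentation and scoring. A synthetic-data
module generates every input with the statistical structure the methods
assume, so the whole pipeline is exercised and tested without any
external data.

# Clone calling from expressed barcodes

The lineage barcode is a 48-bp cassette of eight blocks of four random
bases, each followed by a fixed 2-mer (CT, AC, TC, GT, TG, CA, AT, GC),
expressed on a transcript that also carries the anchor 7-mer `TAGACAT`.
Parsing (`parse_barcode_reads()`) takes the first window within Hamming
distance 1 of the anchor (everything up to and including it is trimmed),
reads the next 48 bp, and rejects reads with a failed invariant 2-mer,
fewer than 48 remaining bases, or an all-G UMI. Each read lands in
exactly one category, which doubles as the QC report.

Sequencing errors are absorbed in two places. First, reads are counted
per cell-UMI-barcode triple and triples with fewer than 5 reads are
dropped (`filter_support()`): an error-bearing variant of a true barcode
rarely recurs identically within one UMI. Second, surviving barcodes are
collapsed by edit distance (`collapse_barcodes()`): each barcode maps to
the most abundant barcode within Levenshtein distance 4 of it, and the
resulting representatives are collapsed once more at distance 2, in a
single pass in decreasing abundance. The pass structure guarantees the
final consensus set is pairwise separated by more than 2 edits, which is
asserted rather than assumed. Ties in abundance are broken
lexicographically so the collapse is deterministic. Cells are assigned
to the clone supported by a plurality of UMIs; tied cells are excluded
(assigning them randomly would make results run-dependent); clones need
at least 5 cells; each clone is assigned to the sample contributing most
of its cells, with that majority fraction reported as purity.

One parsing subtlety: because the anchor search takes the *first*
acceptable window, a random prefix occasionally fakes an anchor
(probability about 1.3% for a 10-bp prefix), shifting the frame and
failing the invariant check. This costs individual reads, not triples,
and is invisible after the support filter; it is the behaviour implied
by trimming at the first match.

# Deviation scores for motif families and gene programs

A cell's accessibility (or expression) in an annotated feature set is
confounded by its sequencing depth and the set's overall abundance. The
deviation score used here, in the chromVAR tradition, compares observed
counts with a depth-matched expectation and standardizes against
matched background sets. For cell $i$ and set $m$ with weights $w_j$:

$$E_{im} = d_i \sum_{j \in m} w_j f_j,\qquad
  r_{im} = \frac{o_{im} - E_{im}}{E_{im}},\qquad
  z_{im} = \frac{r_{im} - \overline{r^{bg}_{i\cdot}}}{\mathrm{sd}(r^{bg}_{i\cdot})}$$

where $d_i$ is the cell's total count, $f_j$ feature $j$'s fraction of
all counts, and the background sets are formed by substituting each
member feature with a matched feature. Motif sets use unit weights over
peaks with 10 abundance bins; gene programs use the topic-gene
probabilities as weights with 20 expression bins and the same 250
background draws.

Two implementation choices matter:

* **Backgrounds are within-bin permutations.** Each of the 250
  background replicates applies one independent permutation of the
  features within abundance bins, rather than sampling features
  per-member with replacement. Permutations keep background sets
  bijective with the original set, so the degenerate all-features set
  scores exactly zero (observed equals expected in every replicate), and
  matching quality is identical otherwise. Sampling is fully determined
  by the `seed` argument.
* **Matching is on mean abundance only.** GC-content matching (part of
  chromVAR's background model for real sequence) is omitted: synthetic
  peaks carry no sequence. On real data with composition covariates
  available, the binning variable is the place to encode them.

Motifs are bagged into families (`bag_motif_families()`) greedily: sort
by cross-cell variability, let each motif join the first more-variable
leader with similarity q-value at or below 0.05 (missing pairs count as
dissimilar; one-directional similarities use the minimum of the two
directions), otherwise found a new family. The result is a partition,
with the most variable member as each family's leader.

Sample-level statistics (`per_sample_stats()`) average single-cell
scores within each sample, define change relative to the mean of
control samples, and test each non-control condition against control by
a two-sided Welch t-test over sample means — Welch because sample-level
n is small and there is no reason to assume equal variances; the
Benjamini-Hochberg adjustment runs across the 50 most variable families
(variability of a family = SD of its per-sample means, the natural
sample-level analogue). Activated-cell fractions use a strict
threshold (score > 1.5); heterogeneity between conditions is tested by
a two-sample Kolmogorov-Smirnov test after downsampling each condition
to 500 cells (conditions with fewer cells are used whole and flagged).
Note that a KS test at these sizes resolves subpopulation shifts of
roughly 15–20% of cells at 3 SD; substantially smaller subpopulations
sit at its detection floor.

Gene programs are fit by latent Dirichlet allocation on raw counts
(`fit_gene_programs()`), via a collapsed Gibbs sampler written for this
package (no topic-model package is part of the declared dependencies).
Model selection across the topic range maximizes the collapsed
log-likelihood $\log P(w, z \mid \alpha, \beta)$ of the final sampler
state; unlike the training-data likelihood of the point estimates, this
quantity penalizes surplus topics and reliably recovers a planted topic
number. The default desk-scale range is 5–15 topics with 150 sweeps,
$\alpha = 50/K$, $\beta = 0.1$; genome-scale analyses would raise the
range (e.g. 30–90) without touching the algorithm. Programs are scored
on cells with the deviation machinery above, and `program_gene_lists()`
extracts the top-150 genes by topic weight (ties by gene index).

# The clonal heritability permutation test

The core statistic asks: is the within-clone spread of a score smaller
than expected if clone labels carried no information? For one feature,

$$V = \left(\mathrm{median}_{c}\; \mathrm{sd}(\text{scores in clone } c)\right)^2,$$

the squared median across clones of the within-clone standard deviation
(n−1 denominator; clones need at least 2 cells, though upstream clone
calling already requires 5). The median-then-square form follows the
source procedure literally; squaring a median of SDs is not the median
of variances, but the monotone transform preserves the permutation
ranks, so the choice affects scale only.

`clonal_heritability()` permutes the cell-to-clone assignment 1000
times — the same permutations for every feature, matching a design where
assignments, not per-feature labels, are shuffled, and halving the
between-feature comparison variance — and summarizes with

$$Z = \frac{V_{obs} - \overline{V_{perm}}}{\mathrm{sd}(V_{perm})},
  \qquad p = 2\,\Phi(-|Z|),$$

with BH adjustment across features. Heritable features have *negative*
Z: clone labels compress within-clone spread. The normal approximation
is the specified form; because the permutation null of a squared median
can be skewed, an exact rank-based permutation p-value is reported
alongside as a diagnostic (`p_empirical`), not used for the FDR. When
the permutation distribution is constant (e.g. a single clone), the
feature is flagged degenerate with p = 1 rather than producing 0/0.

Clone-level comparisons (`compare_clone_distributions()`) summarize each
clone by the median and SD of its cells' scores, compare conditions by
a KS test on the SDs and by median shifts, and count high clones with
median score strictly above 1.25. `correlate_motifs_programs()` averages
motif and program scores per clone and correlates the clone-mean vectors
(Pearson by default, Spearman available), reporting the best program per
motif.

# Neighbourhood enrichment and smoothing

`knn_condition_enrichment()` computes, for each cell, the fraction of
each condition among its k = 100 nearest neighbours (Euclidean, exact
search) minus the global condition fraction over the analysed cells —
the expected value under random assignment. The cell itself is excluded
from its neighbourhood (including it inflates own-condition enrichment
by 1/k); enrichment rows therefore sum to zero exactly. Distance ties
are broken by cell index, making results reproducible to the bit.
`knn_smooth()` averages each cell with its k = 20 neighbours (self
included, the common visualization convention; configurable), and is a
contraction: smoothed values stay inside the input range.

# Footprint post-processing and co-binding

Footprint scores arrive as (peak, 10-bp bin, condition) tables from an
upstream footprinting model; this package consumes, never trains, such
models. Bins whose maximum score across conditions is below 0.2 are
excluded, then scores are quantile-transformed to uniform within each
condition (rank minus one over n minus one; rank-preserving by
construction). Memory sites are bins whose case-minus-matched-control
change is at least 0.2 — the threshold is inclusive — attributed to TF
families through a supplied motif-site map; the condition-control
pairing is explicit configuration, never inferred. Whether the 0.2
change is taken on transformed or raw scores is the caller's choice of
input; the generator's planted gains are calibrated on raw scores and
the transform is validated separately for rank preservation.

Co-binding between two families cross-tabulates peaks by membership in
the two families' memory-site sets; the odds ratio
$(both \times neither)/(first \times second)$ gets a Haldane–Anscombe
0.5 on all cells when any cell is zero (keeping it finite), is
log2-transformed, and, across all pairs, positive values are clipped to
their 10th–90th percentile range and mapped linearly to [0, 1]
(negatives to [−1, 0]; a degenerate percentile range maps the whole
sign class to ±1). The 2×2 is computed over the full filtered peak
universe, not only peaks containing a site. Site spacing
(`site_distances()`) is the set of absolute midpoint differences between
the two families' sites within shared peaks, midpoints at bin start + 5.
`footprint_binding_performance()` sweeps thresholds over per-peak
footprint changes against binary differential-binding labels,
reporting sensitivity and specificity at every observed cutoff (change
at or above threshold predicts positive), after overlapping motif sites
are collapsed to one site carrying the largest absolute change.

# Genomic interval bookkeeping

Summit-based peak construction (`filter_summits()`) pads each summit by
400 bp on either side, keeps summits greedily in decreasing
significance when the padded 801-bp windows do not overlap (ties broken
by chromosome then position; overlap is tested on the padded windows,
before resizing), and emits kept summits as 301-bp peaks (summit ±150,
0-based half-open). Windows running past a chromosome start are clamped
at zero, so a summit within 150 bp of the start yields a shorter peak —
the only exception to the fixed width. Pseudobulking sums raw counts
over cell groups with RPM normalization and an RPM ≥ 10 expression
flag; `variable_peaks()` requires at least 20 raw reads in one sample
and ranks by RPM standard deviation; `zscore_change()` z-scores per
feature across samples (n−1 SD; zero-variance features are flagged, not
silently zeroed) and subtracts the mean control z.

# Spatial tumor identification and scoring

Bins with fewer than 300 reads are dropped and the rest scaled to the
mean retained depth; log2(x+1) values feed a 20-component PCA in which
the marker gene's expression is smoothed over k = 20 neighbours,
z-scored, and thresholded at z ≥ 1 (inclusive) to call adenoma bins.
Tumors are communities of the k = 5 spatial nearest-neighbour graph over
adenoma bins under Louvain modularity clustering.

The Louvain resolution is the one genuinely free parameter. At the
conventional resolution of 1, modularity's resolution limit fragments
any contiguous disc larger than roughly 25 bins into several
communities — a well-known property of modularity on dense local
graphs, confirmed here on synthetic discs. The default is therefore
0.1, which keeps contiguous regions up to roughly a hundred bins (the
scale of a microscopic adenoma at 16-µm bins) as single communities
while distinct, separated regions remain distinct. Oversegmentation of
very large tumors at this default is still possible and surfaces as
extra communities rather than being silently merged. With fewer than
k + 1 adenoma bins no graph is built; a single flagged tumor is
returned.

Tumor program scores reuse the deviation machinery on tumor pseudobulks
(20 expression bins, 250 backgrounds), and tumors with score strictly
above 1.5 are flagged high.

# What the synthetic data emulates — and what it does not

Every generator stores its ground truth alongside the data, so each
downstream stage has a recovery test.

* `simulate_clonal_scores()` draws clone effects at scale `clone_sd`
  for heritable features, adds condition mean shifts and cell noise,
  and can plant an exceptional high-scoring clone subpopulation
  (`frac_high`, shift 2.5) and a condition-specific noise ratio. The
  test geometry (50 clones × 20 cells, 500 features, 50 heritable)
  gives the permutation test a realistic number of clones at organoid
  scale.
* `simulate_barcode_reads()` renders the true cassette layout with
  per-base substitution errors, configurable read support (default 10
  reads per triple, 3 UMIs per cell), decoy reads and poly-G UMIs.
  Founder barcodes are rejection-sampled to pairwise edit distance
  greater than 8, so the distance-4 collapse cannot merge distinct
  clones — the regime the vector's diversity is designed for. Indels
  within reads are not simulated (substitution error dominates the
  platform); the collapse handles them anyway since it uses full
  Levenshtein distance.
* `simulate_counts_and_annotations()` draws per-cell depths log-normal
  and counts multinomial given depth. The multinomial is the Poisson
  model conditioned on the cell total, so per-cell totals equal the
  drawn depth exactly — which makes depth-confounding tests sharp. A
  fraction of case-condition cells carries a multiplicative fold on the
  target family's peaks.
* `simulate_footprints()` plants memory gains of +0.3 at motif sites
  whose two-family co-occurrence follows a prescribed odds ratio
  (Plackett construction), with co-occurring sites a fixed distance
  apart, plus non-memory sites to exercise attribution.
* `simulate_spatial_section()` places well-separated disc tumors on a
  grid; tumor bins elevate the marker (8×) and a 15-gene tumor-identity
  signature (4×), and high tumors additionally elevate a 20-gene
  program (3×). The signature matters: real adenomas differ from normal
  tissue across much of the transcriptome, and without it the PCA
  embedding barely separates non-high tumors from background, which
  leaks marker signal through the k-NN smoothing. About 5% of bins get
  sub-threshold depth to exercise QC.

None of the generators model fragment-level sequencing, GC or chromatin
biophysics, batch effects, doublets, or spatial platform artifacts.
Passing recovery tests on these data shows the *procedures* are
implemented correctly and calibrated under their own assumptions; it
does not certify performance on real data, where background matching
(GC), embedding quality and footprint-model noise dominate.

# Numerical and reproducibility notes

* All randomness flows from integer seeds; generators derive
  independent sub-streams from one master seed and restore the caller's
  RNG state. Identical configuration implies identical output.
* Exact k-NN with ties broken by index; no approximate search at desk
  scale.
* Degenerate cases are explicit: zero-variance features are flagged
  (never divided by), constant permutation nulls report p = 1 with a
  flag, empty memory sets propagate as missing co-binding entries,
  sections that lose every bin to QC raise errors.
* Problem sizes in the test-suite and acceptance runs: 1000 permutations
  on 1000 cells × 500 features for calibration and power; 2000 cells ×
  40 clones for barcode round trips; 2000 × 5000 counts with 250
  backgrounds for the deviation null; 1000 random summit sets against a
  brute-force oracle; 48 × 48 to 90 × 90 spatial grids. These sizes give
  stable statistics for every assertion while keeping a full run in
  minutes on one core.

# Known limitations

* Background matching omits sequence composition (no GC); real-data use
  should supply composition-aware bins.
* The normal approximation for the permutation Z can misstate extreme
  tail p-values when the null is skewed; the reported empirical p is the
  check.
* Louvain resolution trades fragmentation against merging; 0.1 suits
  microscopic-adenoma scales and well-separated lesions, not abutting
  tumors.
* The KS heterogeneity test cannot resolve subpopulations much below
  ~15% at 500 cells per condition.
* LDA point estimates come from the final Gibbs state rather than
  posterior averaging across sweeps; at desk scale the planted-topic
  recovery tests show this is sufficient.
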