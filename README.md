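# clonalmem

Detecting clonally heritable epigenetic states in lineage-barcoded
single-cell multi-omic data.

Tissue injury can leave durable epigenetic marks: after inflammation
resolves, a subset of stem cells retains elevated accessibility at AP-1
(Fos/Jun) transcription-factor motifs, transmitted through cell
divisions and readable years of biology later — including in the tumors
those cells seed. Demonstrating that such a state is *clonally
heritable* requires joint readouts of lineage (expressed DNA barcodes),
chromatin (motif accessibility), and transcriptome (gene programs) from
the same cells, plus a statistic that separates clone-structured
variation from noise.

`clonalmem` implements that computational chain, end to end, for R:

* **Clone calling** — parse expressed 48-bp lineage barcodes (anchor
  `TAGACAT`, staggered invariant 2-mers every 4 bases), filter
  cell-UMI-barcode triples by read support (≥5 reads), collapse
  sequencing errors by two-stage Levenshtein distance (4, then 2), and
  assign cells to clones (≥5 cells) and clones to samples.
* **Deviation scoring** — chromVAR-style background-corrected z-scores
  of motif-family accessibility or gene-program expression, with 250
  abundance-matched background sets (20 expression bins for genes);
  motif bagging into families by similarity q ≤ 0.05; per-sample means,
  changes vs control, Welch t-tests with BH adjustment; activated-cell
  fractions (score > 1.5); KS heterogeneity tests on 500-cell
  downsamples.
* **Clonal heritability** — the core permutation test. The clonal
  variance of a feature is
  `(median over clones of the within-clone SD)^2`; cell-clone labels
  are permuted 1000 times and
  `Z = (obs − mean_shuffled)/sd_shuffled`, `p = 2·pnorm(−|Z|)`,
  with BH FDR across features. Clone-level condition comparisons
  (KS on clone SDs, high-clone fractions at median > 1.25) and
  clone-mean motif–program correlations.
* **k-NN enrichment** — per-cell condition enrichment in an embedding,
  `observed % among 100 nearest neighbours − expected %`, plus k-NN
  smoothing.
* **Footprint co-binding** — 10-bp footprint-bin filtering and
  per-condition quantile transform; memory sites at change ≥ 0.2 over
  matched controls; 2×2 co-occurrence odds ratios per TF-family pair,
  log2-transformed and 10th–90th percentile-normalized to [−1, 1];
  site-spacing distributions; sensitivity/specificity sweeps of
  footprint change against differential binding.
* **Genomic intervals** — summit-padded (±400 bp) greedy
  significance filtering into non-overlapping 301-bp peaks,
  pseudobulking with RPM ≥ 10 filters, top-variable-peak selection,
  z-score changes vs control.
* **Spatial tumors** — 300-read bin QC, marker smoothing over k = 20
  PC-space neighbours, adenoma calls at z ≥ 1, tumor segmentation by
  Louvain communities of the spatial k = 5 graph, and per-tumor program
  scores (high tumors at score > 1.5).
* **Synthetic data** — generators for every input (clone-structured
  scores, barcode reads, counts with motif annotations, footprint
  tables, spatial sections), each storing its ground truth, so the full
  pipeline runs and is tested without external data.

## Worked example

Simulate 600 cells in 30 clones with 20 of 200 features carrying a
planted clone-level variance component, sequence their lineage barcodes
at a 1% error rate, call clones, and test every feature for clonal
heritability:

```r
library(clonalmem)

cfg <- sim_config(seed = 7, n_cells = 600, n_clones = 30,
                  n_features = 200, n_heritable = 20,
                  clone_sd = 1, noise_sd = 1)
sim <- simulate_clonal_scores(cfg)

barcodes <- simulate_clone_barcodes(30, seed = 7)
names(barcodes) <- sort(unique(sim$clone))
reads <- simulate_barcode_reads(sim$clone, barcodes,
                                error_rate = 0.01, seed = 7)
clones <- call_clones(reads)
clones
#> Clone map: 30 clones, 598 assigned cells, 0 ambiguous cells
#> Clone sizes:    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   19.00   20.00   20.00   19.93   20.00   20.00

fit <- clonal_heritability(sim$scores,
                           clones$cell_to_clone[rownames(sim$scores)],
                           n_perm = 1000, seed = 7)
#> Warning: 2 cells without clone labels dropped
summary(fit)
#> Clonal heritability: 20 of 200 features at FDR < 0.05
#> Top features:
#>       feature  observed         Z            p          fdr
#>  feature_0001 0.8422658 -14.01350 1.288927e-44 2.577853e-42
#>  feature_0007 0.9540188 -13.24037 5.129648e-40 5.129648e-38
#>  feature_0015 0.9395765 -11.77301 5.377187e-32 3.584791e-30
#>  ...
```

All 598 barcoded cells are re-assigned to their true clones despite the
sequencing errors, and the 20 features detected at FDR < 0.05 are
exactly the 20 planted heritable ones. Negative Z means the
within-clone spread is smaller than under shuffled clone labels — the
signature of a heritable state. The `observed` column is the clonal
variance statistic itself; here the planted features have within-clone
SD near the cell-noise level (1), against a total SD inflated by the
clone effects.

Per-condition activated-cell fractions for the signature feature come
from the same scores:

```r
activated_fraction(sim$scores[, 1], sim$condition)
#> colitis control
#>    0.17    0.13
```

See the methods vignette (`vignettes/clonal-memory-methods.Rmd`) for
the statistical details of every stage and the design decisions.

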