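# clonaltracker

Simulation and analysis of high-diversity lentiviral DNA barcode clonal
tracking in hematopoietic stem and progenitor cell (HSPC) transplantation
models. In these experiments every transduced HSPC is tagged with a short
random DNA barcode; amplicon sequencing of sorted immune populations
(T, B, myeloid, NK subsets) from blood and tissues (liver, spleen, gut,
lung/BAL, lymph node) then reads out each clone's fractional contribution
to each sample, revealing which clones circulate everywhere and which are
expanded in a single tissue. The package is for researchers running or
reanalysing such studies and covers the complete desk workflow:

- **Synthetic experiments** — library generation, transduction with
  collision accounting, Dirichlet clone sizes, lineage/tissue-bias and
  temporal clonal dynamics, cell sampling, PCR noise, sequencing error,
  multiplexed FASTQ emission with ground truth.
- **Barcode calling** — index demultiplexing, flank-anchored extraction,
  directional Hamming error collapse, read/genome sampling thresholds,
  with an exact read-conservation ledger.
- **Abundance** — fractional abundance, counts-per-million, natural-log
  fractional abundance with explicit zero flooring.
- **Clone tracking** — timepoint-averaged contributions, top-N clone
  sets, tissue-biased clone detection, aggregate top-clone contributions,
  clone-sharing summaries.
- **Multivariate** — hierarchical clustering of top-clone log abundances,
  PCA of CPM profiles, pairwise Pearson correlation matrices.

## The statistics at the core

With a library of diversity `D` labeling `k` cells uniformly, the
probability a cell's barcode is unique is `(1 − 1/D)^(k−1)`; at
`D = 10^7`, `k = 5×10^5` this is ≈ 0.951, the ≥95% unique-labeling regime
these libraries target. Sequencing errors are collapsed by directional
clustering: barcode *b* merges into the highest-count retained barcode
*p* with `Hamming(b, p) ≤ d` and `count(p) ≥ ρ·count(b) − 1` (defaults
`d = 1`, `ρ = 2`). A clone is *tissue-biased* when its timepoint-averaged
fraction in one location exceeds `5×` its fraction in every other
location, with a recorded epsilon guarding zero denominators.

## Worked example

The `analysis/` drivers run a complete synthetic study — 200 clones,
4 tissues × {T, bulk NK} × 2 timepoints, 6 planted fold-10 tissue-biased
clones, 2×10^4 reads/sample:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract.R
Rscript analysis/03_normalize.R
Rscript analysis/04_track.R
Rscript analysis/05_compare.R
Rscript analysis/06_benchmarks.R
```

which prints, stage by stage:

```
library D=10000, transduced k=500, unique labeling 94.0% (closed form 95.1%)
engrafted 200 clones; planted 6 tissue-biased clones, realized folds 6.3-8.7
emitted 320000 reads over 16 samples -> results/run/reads.fastq
reads: 320000 total = 319994 assigned + 5 unassigned-index + 1 flank-failed + 0 length-failed
error collapse moved 10849 reads onto parents; thresholds removed 667 barcodes (2372 reads)
counts matrix: 166 clones x 16 samples
biased-clone calls: 6; planted recovered: 6/6; false: 0
aggregate top-10 self-contribution: 29.5% - 38.8% across locations
PCA variance explained: PC1 34.7%, PC2 28.6%
mean Pearson r within location 0.962 vs between 0.719
```

Reading this: the empirical unique-labeling fraction (94.0%) sits at the
closed form for this small demo library; after error collapse and
thresholds the 320k reads resolve to 166 retained clones (the remaining
engrafted clones fall below the one-cell-equivalent sampling floor); all
6 planted tissue-biased clones — and nothing else — are called at the 5×
threshold; and samples from the same tissue/population correlate far more
strongly (r = 0.96) than samples from different locations (r = 0.72),
the pattern that drives the heat-map and PCA groupings. Tables land under
`results/run/` (counts, abundances, biased clones, top-clone membership
with `*` flags, aggregate contributions, newick dendrogram, PCA
coordinates, correlation matrix). `run_pipeline(demo_run_config())` runs
the same chain as a single call with a manifest of checksums.

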