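---
title: "Methods: simulating and analysing barcode clonal tracking across blood and tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing barcode clonal tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In lentiviral barcode clonal tracking, hematopoietic stem and progenitor
cells (HSPCs) are transduced with a high-diversity library of short
semi-random DNA tags before autologous transplantation. Every engrafted
clone and all of its progeny — T cells, B cells, granulocytes, monocytes,
NK subsets — carry the founder's barcode, so amplicon sequencing of sorted
cell populations from blood and tissue biopsies reads out each clone's
fractional contribution to each sample. This package implements the full
desk side of such a study: a generative simulator that stands in for the
animal experiment, barcode calling from multiplexed FASTQ, abundance
normalization, tissue-bias detection and top-clone tracking, and
multivariate sample comparison. Because raw animal data are not shipped
with the package, the simulator is a first-class, tested component: every
downstream stage is validated against the ground truth it emits.

# The generative model

**Library and labeling.** `generate_library(D, L)` draws `D` distinct
uniform-random barcodes of length `L` (default 35 nt; barcode length and
read layout are construct-specific and fully configurable — nothing
downstream depends on the defaults). Transduction assigns each of `k`
cells a barcode uniformly with replacement; the probability that a given
cell's barcode is unique among the `k` is

$$P(\text{unique}) = (1 - 1/D)^{k-1},$$

which for a library of diversity $10^7$ labeling $5\times10^5$ cells is
about 0.951 — the ≥95% unique-labeling regime these libraries are designed
for. `simulate_transduction()` reports the empirical unique fraction and is
cross-checked against the closed form by Monte Carlo in the tests.

**Clone sizes.** Engrafted clone baseline sizes follow a symmetric
Dirichlet with concentration `alpha = 0.5`. With `alpha < 1` this yields a
few large clones plus a long tail of small ones, the qualitative shape of
polyclonal HSPC output; `alpha` is exposed because real animals differ
widely in clonality.

**Lineage and tissue structure.** Per-sample expected clone weights are
`baseline × lineage multiplier × tissue-bias fold × temporal walk`,
renormalized to sum to 1. Tissue-biased expansions are planted explicitly
(`tissue_bias`: clone, tissue, optional population, fold ≥ 1), and the
realized post-normalization fold of every planted clone is recorded in the
ground truth, since renormalization necessarily shrinks the configured
fold when boosted clones occupy a large share of a sample.

**Temporal dynamics.** Clone sizes wax and wane over serial timepoints via
a per-location log-normal random walk: a location's first timepoint is at
the baseline state and each timepoint transition multiplies the clone
weight by $e^{\mathcal{N}(0, \sigma^2)}$ (default σ = 0.2, giving roughly
±20% per-step drift — visible but stable, matching serially resampled
tissues). σ = 0 yields perfectly stable clones, a property the tests rely
on.

**Sampling and sequencing.** Per sample, `genomes_sampled` cell genome
equivalents are drawn multinomially from the true fractions (default
5×10⁴, the genome count of ~325 ng genomic DNA at ~6.5 pg per diploid
genome, mid-range for a 200–500 ng PCR input). Each sampled molecule gets
a log-normal PCR weight (σ = 0.5 by default); this one-shot weight stands
in for a 28-cycle branching process — it produces equivalent
overdispersion at a fraction of the cost, and the cycle count is retained
in the protocol for provenance only. Reads are then drawn multinomially
over amplified molecule mass and rendered as
`index + 5' flank + barcode + 3' flank` with iid per-base substitution
errors and constant Q37 qualities (the pipeline never uses quality
scores). When PCR σ and the error rate are both zero the allocation
switches to deterministic largest-remainder rounding, so noise-free read
fractions equal true fractions exactly up to integer rounding — which is
what makes the exactness tests possible.

# Barcode calling

**Demultiplexing** assigns a read to the unique sample whose index matches
within `max_index_mm` (default 1) mismatches. At load time the design is
rejected if any two sample indices are within `2 × max_index_mm`, the
condition under which a read could match two samples.
`generate_indices()` produces index sets at a guaranteed pairwise
distance. Every read lands in exactly one ledger class — assigned,
unassigned-index, flank-failed, or length-failed — and the ledger must
reconcile exactly with the input read count.

**Extraction** is positional: both 20-nt constant flanks must match within
`max_flank_mm` (default 2) mismatches at their expected offsets. Indels
are deliberately not searched: with a fixed-length barcode between
anchored flanks, an indel read fails the flank or length check and is
counted rather than rescued.

**Error collapse** uses greedy directional Hamming clustering, the
convention established for UMI deduplication: barcodes are visited in
descending raw-count order (ties lexicographic); a barcode merges into the
highest-raw-count already-retained barcode within Hamming distance `d`
(default 1) whose raw count is at least `ρ·count − 1` (default ρ = 2).
Parent eligibility uses raw, pre-merge counts, which keeps the pass
deterministic and order-invariant; merged reads accumulate into the
parent. The implementation is verified against an exhaustive brute-force
oracle on hundreds of random instances.

**Sampling thresholds.** A clone cannot be observed below one cell
equivalent, so a barcode is retained only if its count is ≥ the flat floor
(default 10 reads) and, when the sample's genome input is known, its
fraction is ≥ `1/genomes_sampled`. Removed barcode and read mass is
reported, and a sample emptied by thresholds is flagged, not an error. The
exact threshold values used in any published pipeline vary; all policy
fields are configurable and recorded in output provenance.

# Abundance representations

Fractional abundance (column-normalized counts), counts-per-million
(fraction × 10⁶), and natural-log fractional abundance. Zeros under the
log are floored at half the smallest nonzero fraction in the matrix — a
display-standard choice that keeps ranks intact and places absences just
below the smallest observation — or at a fixed pseudo-fraction; the floor
actually used is stored in the matrix and in the TSV header
(`#repr=`, `#log_floor=`).

# Clone-level tracking

**Timepoint averaging.** Locations are tissue × population groups; a
clone's contribution to a location is its arithmetic mean fraction over
that location's timepoints, with absences counting as zero.

**Top clones.** Per sample, the N (default 10) largest-fraction barcodes,
ties broken lexicographically; the union over samples defines the heat-map
row set, and a star matrix records per-sample membership.

**Tissue-biased clones.** A clone is called biased toward a focal location
when its averaged fraction there exceeds the threshold (default 5) times
its fraction in *every* other location:
`fold = focal / max(epsilon, max_other)`. The max comparison is the strict
reading of "expanded compared to all other locations"; a mean comparison
is available behind a flag. Zero denominators use a dataset-derived
epsilon — one read in the deepest sample — rather than an infinite fold,
and the epsilon is recorded in each call for audit. Screening is
restricted by default to clones that are top-N somewhere, mirroring the
focus on the highest-contributing clones and avoiding epsilon-driven
artifacts among barely-detected clones; `screen = "all"` lifts the
restriction. The 5× rule is a deterministic descriptive filter, not a
statistical test; its error behavior is characterized by simulation
(below) instead of multiple-testing machinery.

**Aggregate contributions and sharing.** The aggregate top-10 statistic
ranks an index location's clones by mean fraction over its timepoints and
sums those clones' fractions in every location. Clone sharing between two
sample groups uses a presence floor on the mean fraction and reports
counts, Jaccard, and the shared clones' mass per group.

# Multivariate comparison

Heat-map rows are ordered by agglomerative clustering of Euclidean
distances between log fractional abundances; complete linkage is the
default (single/average/Ward configurable) and rows are pre-sorted by
label so tied merges resolve deterministically. PCA of CPM profiles is
clone-centered and unscaled by default (a log-CPM/scaled mode exists), and
each component's sign is fixed by forcing its largest-magnitude loading
positive so outputs are reproducible. Pairwise Pearson correlations are
computed on linear fractional abundances over the union of all retrieved
clones — "contributions" are linear quantities — with a log mode behind a
flag; zero-variance samples yield NA with a warning rather than a
fabricated 0.

# Benchmark experiments and their design

`recovery_experiment()` runs the full path — 200 clones, 8 samples
(2 tissues × 2 populations × 2 timepoints), 10⁵ reads/sample, 0.1%
per-base error, PCR σ = 0.5 — and measures per-sample Pearson r between
recovered and true fractions (clones lost to thresholds count as zero).
These sizes keep the experiment comfortably inside interactive runtimes
while leaving each noise source at realistic strength.

`bias_experiment()` plants 10 fold-10 clones across liver, jejunum and
BAL, drawn from mid-sized baseline clones (baseline ranks 21–30), with
temporal σ = 0.2. Two deliberate design points: planted clones are spread
over three tissues because stacking ten boosted clones into one tissue
both crowds the top-10 screen and shrinks every realized fold through
renormalization; and they are drawn from mid-sized clones because a clone
whose focal abundance falls below one sampled genome is undetectable at
any threshold — planting biases in unobservable clones would measure the
sampling depth, not the detector. Null replicates rerun the identical
design without planted biases and count calls per location. The null and
planted runs use the count-level sampling path (multinomial genomes,
log-normal PCR, multinomial reads); the read-string path with sequencing
error and extraction is exercised by the recovery experiment, and bias
detection consumes only fractions.

# What the simulator does and does not emulate

It emulates: heavy-tailed clone sizes, lineage- and tissue-restricted
output, serial-timepoint stability with drift, finite cell sampling, PCR
overdispersion, substitution sequencing error, and multiplexed pooling.
It does not emulate: lentiviral integration-site effects on clone fitness,
GFP expression and sorting purity, indels or quality-correlated error
profiles, paired-end reads, PCR chimeras, or cross-sample index hopping.
Passing tests therefore demonstrate correctness of the analysis under a
well-specified generative model — not robustness to every artifact of
real amplicon data, where flank-anchored extraction and directional
collapse are known to be conservative but not exhaustive defenses.

# Numerical and degenerate-input conventions

Ties break by descending count then lexicographic barcode everywhere a
rank matters. All generators are bit-reproducible under a fixed seed, and
the pipeline's tabular outputs are byte-identical across reruns of the
same seed and configuration. Fraction columns must sum to 1 within 1e-9;
CPM to 10⁶ within 1e-3. Empty samples are flagged and excluded rather
than fatal; an all-zero matrix is an error. Rejected reads are data
(counted in the ledger), never exceptions.

# Known limitations

De novo barcode calling only — matching against a known library whitelist
is a possible extension; single-end, fixed-layout reads; no rarefaction or
variance-stabilizing normalizations; the 5× bias rule inherits the
arbitrariness of any fold threshold and should be read alongside the
simulation-based false-call characterization rather than as a calibrated
test.
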