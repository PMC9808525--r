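Package: clonaltracker
Title: Clonal Tracking of Barcoded Hematopoietic Stem Cell Output Across Blood and Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of high-diversity lentiviral DNA barcode
    clonal tracking experiments in hematopoietic stem and progenitor cell
    (HSPC) transplantation models. Generates complete synthetic barcoded
    transplantation experiments (library, transduction, clonal dynamics
    across tissues and immune populations, cell sampling, PCR amplification
    noise, sequencing error) as FASTQ plus ground truth; calls barcodes from
    multiplexed amplicon reads (index demultiplexing, flank-anchored
    extraction, directional Hamming error collapse, sampling thresholds);
    normalizes clone counts to fractional abundance, counts-per-million and
    natural-log fractional abundance; detects tissue-biased clonal
    expansions, tracks top-clone sets and aggregate top-clone contributions
    across populations; and compares samples by hierarchical clustering,
    principal component analysis and pairwise Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
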