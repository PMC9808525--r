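#!/usr/bin/env Rscript
# Stage 2: call barcodes from the pooled FASTQ.
# Demultiplexes by index, extracts barcodes between the constant flanks,
# collapses sequencing errors (directional Hamming clustering) and applies
# the read/genome sampling thresholds.

source("analysis/00_config.R")

sheet <- load_sample_sheet(file.path(RESULTS_DIR, "sample_sheet.tsv"))
counts <- call_barcodes(file.path(RESULTS_DIR, "reads.fastq"),
                        study_design(), sheet, study_policy())
st <- attr(counts, "extraction_stats")
message(sprintf(
  "reads: %d total = %d assigned + %d unassigned-index + %d flank-failed + %d length-failed",
  st$total, sum(st$assigned), st$unassigned_index, st$flank_failed,
  st$length_failed))
message(sprintf(
  "error collapse moved %d reads onto parents; thresholds removed %d barcodes (%d reads)",
  st$collapsed_reads, st$threshold_removed_barcodes,
  st$threshold_removed_reads))
message(sprintf("counts matrix: %d clones x %d samples",
                nrow(counts), ncol(counts)))

write_counts_matrix(counts, file.path(RESULTS_DIR, "counts.tsv"))
jsonlite::write_json(unclass(st), file.path(RESULTS_DIR,
                                            "extraction_stats.json"),
                     auto_unbox = TRUE, digits = NA)
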