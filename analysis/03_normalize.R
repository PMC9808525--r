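#!/usr/bin/env Rscript
# Stage 3: normalize clone counts into the three abundance representations:
# fractional abundance, counts-per-million, natural-log fractional
# abundance (zeros floored at half the minimum nonzero fraction).

source("analysis/00_config.R")

counts <- read_counts_matrix(file.path(RESULTS_DIR, "counts.tsv"))
frac <- to_fractional_abundance(counts)
cpm <- to_cpm(counts)
logf <- log_fractional_abundance(frac)

write_abundance(frac, file.path(RESULTS_DIR, "fraction.tsv"))
write_abundance(cpm, file.path(RESULTS_DIR, "cpm.tsv"))
write_abundance(logf, file.path(RESULTS_DIR, "log_fraction.tsv"))
message(sprintf("normalized %d clones x %d samples; log zero-floor = %.3g",
                nrow(frac), ncol(frac), attr(logf, "log_floor")))
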