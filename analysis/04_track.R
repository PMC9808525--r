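#!/usr/bin/env Rscript
# Stage 4: clone-level tracking statistics.
# Timepoint-averaged abundances per location, top-10 clone sets, tissue-
# biased clone calls at the 5x threshold, aggregate top-10 contributions,
# and a check of the calls against the simulation's planted biases.

source("analysis/00_config.R")

sheet <- load_sample_sheet(file.path(RESULTS_DIR, "sample_sheet.tsv"))
counts <- read_counts_matrix(file.path(RESULTS_DIR, "counts.tsv"))
frac <- read_abundance(file.path(RESULTS_DIR, "fraction.tsv"))

avg <- timepoint_average(frac, sheet)
tc <- top_clones(frac, n = 10)
calls <- detect_biased_clones(avg, threshold = 5, counts = counts)

star_df <- data.frame(barcode = rownames(tc$star),
                      ifelse(tc$star, "*", ""),
                      check.names = FALSE, stringsAsFactors = FALSE)
write.table(star_df, file.path(RESULTS_DIR, "top_clone_membership.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(calls, file.path(RESULTS_DIR, "biased_clones.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

aggs <- do.call(rbind, lapply(colnames(avg), function(l) {
  parts <- strsplit(l, ":", fixed = TRUE)[[1]]
  a <- aggregate_top_contribution(frac, sheet, parts[1], parts[2], n = 10)
  data.frame(index_location = l, a$contributions)
}))
write.table(aggs, file.path(RESULTS_DIR, "aggregate_contributions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path(RESULTS_DIR, "truth.json"),
                             simplifyVector = TRUE)
planted <- paste(truth$biased$barcode,
                 paste(truth$biased$tissue, truth$biased$population,
                       sep = ":"))
called <- paste(calls$barcode, calls$location)
message(sprintf("biased-clone calls: %d; planted recovered: %d/%d; false: %d",
                nrow(calls), sum(planted %in% called), length(planted),
                sum(!called %in% planted)))
self <- aggs[aggs$index_location == aggs$location, ]
message(sprintf("aggregate top-10 self-contribution: %.1f%% - %.1f%% across locations",
                100 * min(self$contribution), 100 * max(self$contribution)))
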