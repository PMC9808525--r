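# Shared configuration for the analysis drivers (01-06). Sourced, not run.
# A mid-sized synthetic study: 4 tissues x {T cells, bulk NK} x 2 serial
# timepoints, 200 engrafted clones, planted tissue-biased T and NK clones.

library(clonaltracker)

RESULTS_DIR <- "results/run"
SEED <- 20260922L

study_sheet <- function() {
  grid <- expand.grid(tissue = c("PB", "liver", "spleen", "jejunum"),
                      population = c("T", "NK_bulk"),
                      timepoint = c(12, 14), stringsAsFactors = FALSE)
  sample_sheet(
    sample_id = sprintf("%s_%s_%dm", grid$tissue, grid$population,
                        grid$timepoint),
    animal = "SIM01",
    tissue = grid$tissue,
    population = grid$population,
    timepoint_months = grid$timepoint,
    index_seq = generate_indices(nrow(grid), len = 8, min_dist = 3,
                                 seed = SEED),
    genomes_sampled = 5e4)
}

study_dynamics <- function() {
  dynamics_config(
    n_clones = 200, alpha = 0.5, temporal_sigma = 0.2,
    tissue_bias = data.frame(
      baseline_rank = c(21, 24, 27, 30, 33, 36),
      tissue = rep(c("liver", "jejunum"), 3),
      population = rep(c("T", "T", "NK_bulk"), 2),
      fold = 10))
}

study_protocol <- function() {
  sequencing_protocol(genomes_sampled = 5e4, pcr_sigma = 0.5,
                      reads_per_sample = 2e4, error_rate = 0.001)
}

study_design <- function() barcode_design()
study_policy <- function() threshold_policy()
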