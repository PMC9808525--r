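#' Benchmark sample sheet used by the recovery and bias experiments
#' @noRd
benchmark_sheet <- function(tissues, populations, seed,
                            timepoints = c(12, 14), genomes = 5e4) {
  grid <- expand.grid(tissue = tissues, population = populations,
                      timepoint = timepoints, stringsAsFactors = FALSE)
  sample_sheet(
    sample_id = sprintf("%s_%s_%dm", grid$tissue, grid$population,
                        grid$timepoint),
    animal = "SIM01",
    tissue = grid$tissue,
    population = grid$population,
    timepoint_months = grid$timepoint,
    index_seq = generate_indices(nrow(grid), len = 8, min_dist = 3,
                                 seed = seed),
    genomes_sampled = genomes)
}

#' End-to-end recovery benchmark
#'
#' Simulates a 200-clone experiment over 8 samples (2 tissues x 2
#' populations x 2 timepoints) at 1e5 reads per sample with 0.1% per-base
#' sequencing error and log-normal PCR noise (sigma 0.5), runs the full
#' barcode-calling pipeline on the emitted FASTQ, and reports the Pearson
#' correlation between recovered and true fractional abundances per sample
#' (clones lost to thresholds count as 0) plus the read-conservation
#' ledger.
#'
#' @param seed integer seed controlling the whole experiment.
#' @param reads_per_sample sequencing depth (default 1e5).
#' @return List: `per_sample_r`, `stats` (extraction stats),
#'   `conservation_ok`, `counts`, `truth`.
#' @export
recovery_experiment <- function(seed, reads_per_sample = 1e5) {
  seed <- as.integer(seed)
  sheet <- benchmark_sheet(c("PB", "liver"), c("T", "NK_bulk"), seed)
  lib <- generate_library(10000, 35, seed = seed + 1L)
  asn <- simulate_transduction(lib, 500, seed = seed + 2L)
  truth <- simulate_clonal_dynamics(
    asn, dynamics_config(200, alpha = 0.5, temporal_sigma = 0.2),
    sheet, seed = seed + 3L)
  proto <- sequencing_protocol(genomes_sampled = 5e4, pcr_sigma = 0.5,
                               reads_per_sample = reads_per_sample,
                               error_rate = 0.001)
  des <- barcode_design()
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  simulate_sequencing(truth, sheet, proto, des, fq, seed = seed + 4L)
  counts <- call_barcodes(fq, des, sheet, threshold_policy())
  frac <- to_fractional_abundance(counts)
  per_sample_r <- vapply(colnames(frac), function(s) {
    rec <- stats::setNames(rep(0, nrow(truth$fractions)),
                           rownames(truth$fractions))
    common <- intersect(rownames(frac), names(rec))
    rec[common] <- frac[common, s]
    stats::cor(rec, truth$fractions[, s])
  }, numeric(1))
  st <- attr(counts, "extraction_stats")
  list(per_sample_r = per_sample_r,
       stats = st,
       conservation_ok = sum(st$assigned) + st$unassigned_index +
         st$flank_failed + st$length_failed == st$total,
       counts = counts,
       truth = truth)
}

#' Tissue-bias detection benchmark
#'
#' Simulates 200 clones over 4 tissues (PB, liver, jejunum, BAL; T cells,
#' 2 timepoints each) with, optionally, 10 planted fold-10 tissue-biased
#' clones spread over the three non-blood tissues, drawn from mid-sized
#' baseline clones (baseline ranks 21-30) so the planted expansions are
#' observable at the configured sampling depth. Sampling, PCR noise and
#' read allocation run at count level (1e5 reads/sample, PCR sigma 0.5);
#' sampling thresholds are applied, and biased clones are called at the
#' given fold threshold on timepoint-averaged fractions.
#'
#' @param seed integer seed.
#' @param planted plant the 10 biased clones (`FALSE` gives a null run).
#' @param threshold bias fold threshold (default 5).
#' @return List: `sensitivity` (fraction of planted (clone, tissue) pairs
#'   called; `NA` for null runs), `false_calls`, `n_locations`, `calls`,
#'   `truth`.
#' @export
bias_experiment <- function(seed, planted = TRUE, threshold = 5) {
  seed <- as.integer(seed)
  sheet <- benchmark_sheet(c("PB", "liver", "jejunum", "BAL"), "T", seed)
  lib <- generate_library(10000, 35, seed = seed + 1L)
  asn <- simulate_transduction(lib, 500, seed = seed + 2L)
  bias <- if (planted) {
    data.frame(baseline_rank = 21:30,
               tissue = rep(c("liver", "jejunum", "BAL"), length.out = 10),
               fold = 10)
  }
  truth <- simulate_clonal_dynamics(
    asn, dynamics_config(200, alpha = 0.5, temporal_sigma = 0.2,
                         tissue_bias = bias),
    sheet, seed = seed + 3L)
  proto <- sequencing_protocol(genomes_sampled = 5e4, pcr_sigma = 0.5,
                               reads_per_sample = 1e5, error_rate = 0)
  tallies <- lapply(seq_len(nrow(sheet)), function(s) {
    with_seed_(seed + 10L + s, {
      r <- simulate_sample_counts(truth$fractions[, s], proto)
      apply_sampling_threshold(r[r > 0], sheet$genomes_sampled[s],
                               threshold_policy())$counts
    })
  })
  names(tallies) <- sheet$sample_id
  counts <- build_counts_matrix(tallies, sheet)
  frac <- to_fractional_abundance(counts)
  avg <- timepoint_average(frac, sheet)
  calls <- detect_biased_clones(avg, threshold = threshold, counts = counts)
  call_keys <- paste(calls$barcode, calls$location)
  if (planted) {
    planted_keys <- paste(truth$biased$barcode,
                          loc_label(truth$biased$tissue, "T"))
    sensitivity <- mean(planted_keys %in% call_keys)
    false_calls <- sum(!call_keys %in% planted_keys)
  } else {
    sensitivity <- NA_real_
    false_calls <- length(call_keys)
  }
  list(sensitivity = sensitivity, false_calls = false_calls,
       n_locations = ncol(avg), calls = calls, truth = truth)
}
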