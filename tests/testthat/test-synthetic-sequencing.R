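noise_free_protocol <- function(reads = 2000, genomes = 1000) {
  sequencing_protocol(genomes_sampled = genomes, pcr_sigma = 0,
                      reads_per_sample = reads, error_rate = 0)
}

small_truth <- function(sheet, n_clones = 20, sigma = 0, seed = 4) {
  asn <- simulate_transduction(generate_library(500, 35, seed = seed),
                               100, seed = seed + 1)
  simulate_clonal_dynamics(asn, dynamics_config(n_clones,
                                                temporal_sigma = sigma),
                           sheet, seed = seed + 2)
}

test_that("noise-free sequencing reproduces truth exactly", {
  sheet <- tiny_sheet()[1:2, ]
  tr <- small_truth(sheet, n_clones = 3)
  # force exact fractions 0.5/0.3/0.2
  tr$fractions[, 1] <- c(0.5, 0.3, 0.2)
  tr$fractions[, 2] <- c(0.5, 0.3, 0.2)
  des <- barcode_design()
  fq <- tempfile(fileext = ".fastq")
  sim <- simulate_sequencing(tr, sheet, noise_free_protocol(2000), des, fq)
  expect_equal(unname(sim$allocation[, 1]), c(1000L, 600L, 400L))
  counts <- call_barcodes(fq, des, sheet,
                          threshold_policy(floor = 0, genome_floor = FALSE))
  f <- to_fractional_abundance(counts)
  expect_equal(unname(f[rownames(tr$fractions), 1]), c(0.5, 0.3, 0.2))
  stats <- attr(counts, "extraction_stats")
  expect_equal(sum(unlist(stats$assigned)), stats$total)
})

test_that("a single clone at fraction 1 yields only its exact read", {
  sheet <- tiny_sheet()[1, , drop = FALSE]
  tr <- small_truth(sheet, n_clones = 1)
  des <- barcode_design()
  fq <- tempfile(fileext = ".fastq")
  simulate_sequencing(tr, sheet, noise_free_protocol(500), des, fq)
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  expected <- paste0(sheet$index_seq, des$flank5,
                     rownames(tr$fractions), des$flank3)
  expect_length(reads, 500)
  expect_identical(unique(unname(reads)), expected)
})

test_that("every emitted read's index matches exactly one sample", {
  sheet <- tiny_sheet()[1:2, ]
  tr <- small_truth(sheet, n_clones = 10)
  des <- barcode_design()
  fq <- tempfile(fileext = ".fastq")
  simulate_sequencing(tr, sheet, noise_free_protocol(300), des, fq)
  idx <- substr(as.character(Biostrings::readDNAStringSet(fq,
                                                          format = "fastq")),
                1, des$index_len)
  matches <- outer(idx, sheet$index_seq, `==`)
  expect_true(all(rowSums(matches) == 1))
})

test_that("duplicate indices abort, fixed seeds give identical FASTQ", {
  sheet <- tiny_sheet()[1:2, ]
  tr <- small_truth(sheet, n_clones = 5)
  des <- barcode_design()
  bad <- sheet
  bad$index_seq <- rep(sheet$index_seq[1], 2)
  expect_error(simulate_sequencing(tr, bad, noise_free_protocol(100), des,
                                   tempfile()), "duplicate|ambiguous")
  p <- sequencing_protocol(genomes_sampled = 500, pcr_sigma = 0.5,
                           reads_per_sample = 500, error_rate = 0.005)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  f3 <- tempfile(fileext = ".fastq")
  simulate_sequencing(tr, sheet, p, des, f1, seed = 77)
  simulate_sequencing(tr, sheet, p, des, f2, seed = 77)
  simulate_sequencing(tr, sheet, p, des, f3, seed = 78)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(f3))))
})

test_that("stochastic count-level sampling stays close to truth", {
  f <- c(A = 0.5, B = 0.3, C = 0.2)
  p <- sequencing_protocol(genomes_sampled = 5e4, pcr_sigma = 0.5,
                           reads_per_sample = 1e5, error_rate = 0)
  reads <- withr::with_seed(31, simulate_sample_counts(f, p))
  expect_identical(sum(reads), 100000L)
  obs <- reads / sum(reads)
  # 99% multinomial CI per clone at this depth (PCR noise widens it; use
  # genome-count binomial sd which dominates)
  sd_f <- sqrt(f * (1 - f) / p$genomes_sampled)
  expect_true(all(abs(obs - f) < 4 * sd_f + 0.01))
})
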