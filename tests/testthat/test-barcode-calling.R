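test_that("single-read extraction honors flanks and layout length", {
  des <- barcode_design(index_len = 4, flank5 = "ACGTACGT",
                        flank3 = "TTGGCCAA", barcode_len = 6,
                        max_flank_mm = 1)
  bc <- "AAACCC"
  read <- paste0("GGGG", "ACGTACGT", bc, "TTGGCCAA")
  expect_identical(extract_barcode(read, des)$barcode, bc)
  # flank carrying max+1 mismatches
  bad5 <- paste0("GGGG", "TTGTACGT", bc, "TTGGCCAA")
  expect_identical(extract_barcode(bad5, des)$reason, "flank_failed")
  expect_identical(extract_barcode("GGGGACGT", des)$reason, "length_failed")
})

test_that("demultiplexing assigns by index within tolerance, else unassigned", {
  sheet <- tiny_sheet()[1:2, ]
  des <- barcode_design(index_len = 8, barcode_len = 6, max_index_mm = 0)
  bc <- "ACACAC"
  mk <- function(idx) paste0(idx, des$flank5, bc, des$flank3)
  res <- demultiplex_extract(c(mk(sheet$index_seq[1]), mk("NOTANIDX")),
                             des, sheet)
  expect_equal(unname(res$stats$assigned[1]), 1)
  expect_equal(res$stats$unassigned_index, 1)
  expect_equal(res$stats$total, 2)
  # two indices within 2*max_index_mm is an ambiguous design
  des1 <- barcode_design(index_len = 8, barcode_len = 6, max_index_mm = 2)
  close_sheet <- sheet
  close_sheet$index_seq <- c("AAAAAAAA", "AAAAAAAT")
  expect_error(demultiplex_extract(mk("AAAAAAAA"), des1, close_sheet),
               "ambiguous")
})

test_that("assigned counts under sequencing error match the retention model", {
  sheet <- tiny_sheet()
  tr <- local({
    asn <- simulate_transduction(generate_library(500, 35, seed = 21), 100,
                                 seed = 22)
    simulate_clonal_dynamics(asn, dynamics_config(20), sheet, seed = 23)
  })
  e <- 0.004
  p <- sequencing_protocol(genomes_sampled = 2500, pcr_sigma = 0,
                           reads_per_sample = 2500, error_rate = e)
  des <- barcode_design()
  fq <- tempfile(fileext = ".fastq")
  sim <- simulate_sequencing(tr, sheet, p, des, fq, seed = 31)
  res <- demultiplex_extract(fq, des, sheet)
  # a read is assigned iff its index has <=1 error and each flank <=2
  p_idx <- stats::pbinom(1, 8, e)
  p_flank <- stats::pbinom(2, 20, e)
  p_pass <- p_idx * p_flank^2
  for (s in seq_len(nrow(sheet))) {
    n <- sum(sim$allocation[, s])
    expect_lt(abs(res$stats$assigned[s] - n * p_pass),
              3 * sqrt(n * p_pass * (1 - p_pass)) + 1)
  }
  st <- res$stats
  expect_equal(sum(st$assigned) + st$unassigned_index + st$flank_failed +
                 st$length_failed, st$total)
})

test_that("directional collapse applies the count-ratio rule", {
  pol <- threshold_policy(d = 1, rho = 2)
  x <- c(AAAAAA = 1000L, AAAAAT = 5L)
  expect_identical(collapse_errors(x, pol), c(AAAAAA = 1005L))
  far <- c(AAAAAA = 1000L, TTTAAA = 900L)  # Hamming 3 apart
  expect_identical(sort(collapse_errors(far, pol)), sort(far))
  # ratio rule: 1000 vs 600 at Hamming 1 must NOT merge (1000 < 2*600-1)
  peers <- c(AAAAAA = 1000L, AAAAAT = 600L)
  expect_identical(sort(collapse_errors(peers, pol)), sort(peers))
  expect_error(collapse_errors(c(AAA = 5L, AAAA = 3L)), "unequal")
})

test_that("collapse matches brute force, conserves reads, ignores order", {
  for (i in 1:60) {
    withr::with_seed(3000 + i, {
      n <- sample(2:20, 1)
      bcs <- unique(random_barcodes(n, 6))
      counts <- stats::setNames(as.integer(sample(1:1000, length(bcs),
                                                  replace = TRUE)), bcs)
      d <- sample(1:2, 1)
      rho <- sample(c(1.5, 2), 1)
      got <- collapse_errors(counts, threshold_policy(d = d, rho = rho))
      want <- oracle_collapse(counts, d, rho)
      expect_identical(got[order(names(got))], want[order(names(want))])
      expect_identical(sum(got), sum(counts))
      expect_lte(length(got), length(counts))
      shuffled <- counts[sample(length(counts))]
      got2 <- collapse_errors(shuffled, threshold_policy(d = d, rho = rho))
      expect_identical(got2[order(names(got2))], got[order(names(got))])
    })
  }
})

test_that("sampling thresholds drop barcodes below read and genome floors", {
  pol <- threshold_policy(floor = 10, genome_floor = TRUE)
  counts <- c(A = 50L, B = 150L, C = 999800L)
  res <- apply_sampling_threshold(counts, genomes_sampled = 1e4, pol)
  # 1e6 reads at 1e4 genomes: fraction floor 1e-4 = 100 reads
  expect_identical(names(res$counts), c("B", "C"))
  expect_equal(res$removed_reads, 50)
  expect_identical(names(apply_sampling_threshold(c(X = 5L), NA, pol)$counts),
                   character(0))
  all_low <- apply_sampling_threshold(c(X = 3L, Y = 2L), NA, pol)
  expect_true(all_low$empty)
  expect_equal(all_low$removed_barcodes, 2)
})

test_that("counts matrix assembles the union with zeros and provenance", {
  sheet <- tiny_sheet()[1:2, ]
  m1 <- build_counts_matrix(stats::setNames(list(c(AAA = 3L), NULL),
                                            sheet$sample_id)[1],
                            sheet[1, , drop = FALSE])
  expect_equal(dim(m1), c(1, 1))
  expect_equal(unname(m1[1, 1]), 3L)
  tal <- stats::setNames(list(c(AAA = 1L), c(TTT = 2L)), sheet$sample_id)
  m2 <- build_counts_matrix(tal, sheet)
  expect_equal(dim(m2), c(2, 2))
  expect_equal(unname(m2["AAA", ]), c(1L, 0L))
  expect_equal(unname(m2["TTT", ]), c(0L, 2L))
  expect_error(build_counts_matrix(tal[1], sheet), "missing sample")
})

test_that("end-to-end noise-free calling equals the generator allocation", {
  sheet <- tiny_sheet()
  tr <- local({
    asn <- simulate_transduction(generate_library(500, 35, seed = 41), 150,
                                 seed = 42)
    simulate_clonal_dynamics(asn, dynamics_config(40, temporal_sigma = 0.2),
                             sheet, seed = 43)
  })
  p <- sequencing_protocol(genomes_sampled = 2000, pcr_sigma = 0,
                           reads_per_sample = 4000, error_rate = 0)
  des <- barcode_design()
  fq <- tempfile(fileext = ".fastq")
  sim <- simulate_sequencing(tr, sheet, p, des, fq)
  counts <- call_barcodes(fq, des, sheet,
                          threshold_policy(floor = 0, genome_floor = FALSE))
  alloc <- sim$allocation[rowSums(sim$allocation) > 0, , drop = FALSE]
  expect_identical(counts[order(rownames(counts)), ],
                   alloc[order(rownames(alloc)), ])
})
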