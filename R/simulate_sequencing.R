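#' Describe the barcode-retrieval sequencing protocol
#'
#' @param genomes_sampled cell genome equivalents drawn into the barcode PCR
#'   per sample (the sampling-depth limit on clone detection). Default 5e4,
#'   the genome-equivalent count of roughly 325 ng genomic DNA at ~6.5 pg
#'   per diploid genome, mid-range of typical 200-500 ng PCR inputs.
#' @param pcr_cycles PCR cycle count, kept for provenance (default 28).
#' @param pcr_sigma log-normal sigma of the per-molecule PCR amplification
#'   weight (0 = noiseless amplification).
#' @param reads_per_sample sequencing reads allocated to each sample.
#' @param error_rate iid per-base substitution error rate, in `[0, 0.25)`.
#' @return A `sequencing_protocol` list.
#' @export
sequencing_protocol <- function(genomes_sampled = 5e4, pcr_cycles = 28,
                                pcr_sigma = 0.5, reads_per_sample = 1e5,
                                error_rate = 0.001) {
  stopifnot(genomes_sampled >= 1, pcr_cycles >= 0, pcr_sigma >= 0,
            reads_per_sample >= 1, error_rate >= 0, error_rate < 0.25)
  structure(list(genomes_sampled = genomes_sampled,
                 pcr_cycles = pcr_cycles,
                 pcr_sigma = pcr_sigma,
                 reads_per_sample = reads_per_sample,
                 error_rate = error_rate),
            class = "sequencing_protocol")
}

#' Describe the amplicon read architecture
#'
#' Reads are laid out as `index + 5' flank + barcode + 3' flank`: a
#' per-sample index from the indexed forward primer, constant vector
#' sequence flanking the barcode on both sides, and the barcode itself.
#'
#' @param index_len index length (default 8).
#' @param flank5,flank3 constant flank sequences.
#' @param barcode_len barcode length `L` (default 35).
#' @param max_flank_mm maximum mismatches tolerated per flank (default 2).
#' @param max_index_mm maximum index mismatches for demultiplexing
#'   (default 1).
#' @return A `barcode_design` list; `read_len` gives the full layout length.
#' @export
barcode_design <- function(index_len = 8, flank5 = DEFAULT_FLANK5,
                           flank3 = DEFAULT_FLANK3, barcode_len = 35,
                           max_flank_mm = 2, max_index_mm = 1) {
  stopifnot(index_len >= 1, barcode_len >= 1,
            max_flank_mm >= 0, max_index_mm >= 0,
            !grepl("[^ACGT]", flank5), !grepl("[^ACGT]", flank3))
  structure(list(index_len = as.integer(index_len),
                 flank5 = flank5, flank3 = flank3,
                 barcode_len = as.integer(barcode_len),
                 max_flank_mm = as.integer(max_flank_mm),
                 max_index_mm = as.integer(max_index_mm),
                 read_len = as.integer(index_len + nchar(flank5) +
                                         barcode_len + nchar(flank3))),
            class = "barcode_design")
}

#' Count-level sampling + PCR + sequencing of one sample
#'
#' Draws `genomes_sampled` cells multinomially from the true clone
#' fractions, weights each sampled molecule by a log-normal PCR
#' amplification factor, and draws `reads_per_sample` reads multinomially
#' over the amplified molecule mass. With `pcr_sigma = 0` and
#' `error_rate = 0` the allocation is deterministic largest-remainder
#' rounding, so read fractions equal true fractions up to integer rounding.
#'
#' @param fractions true clone fractions (sums to 1).
#' @param protocol a [sequencing_protocol()].
#' @return Integer vector of reads per clone (same length/names as
#'   `fractions`).
#' @export
simulate_sample_counts <- function(fractions, protocol) {
  stopifnot(abs(sum(fractions) - 1) < 1e-6)
  G <- protocol$genomes_sampled
  R <- protocol$reads_per_sample
  if (protocol$pcr_sigma == 0 && protocol$error_rate == 0) {
    genomes <- lr_alloc(fractions, G)
    reads <- lr_alloc(genomes, R)
  } else {
    genomes <- as.integer(stats::rmultinom(1, G, fractions))
    if (protocol$pcr_sigma == 0) {
      mass <- as.numeric(genomes)
    } else {
      # per-molecule log-normal amplification weight, summed per clone
      nz <- which(genomes > 0)
      mass <- numeric(length(genomes))
      if (length(nz)) {
        w <- stats::rlnorm(sum(genomes[nz]), 0, protocol$pcr_sigma)
        mass[nz] <- as.numeric(
          tapply(w, rep(seq_along(nz), genomes[nz]), sum))
      }
    }
    reads <- if (sum(mass) == 0) integer(length(fractions)) else
      as.integer(stats::rmultinom(1, R, mass))
  }
  names(reads) <- names(fractions)
  reads
}

#' Simulate pooled amplicon sequencing of a whole experiment
#'
#' For every sample in the sheet, samples cells, applies PCR noise,
#' allocates reads ([simulate_sample_counts()]), renders each read as
#' `index + flank5 + barcode + flank3`, applies iid per-base substitution
#' errors, and writes one pooled FASTQ (constant Q37 qualities). Ground
#' truth is untouched.
#'
#' @param truth a `simulation_truth` from [simulate_clonal_dynamics()].
#' @param sheet the [sample_sheet()]; `index_seq` must be distinct and match
#'   `design$index_len`.
#' @param protocol a [sequencing_protocol()].
#' @param design a [barcode_design()]; `barcode_len` must equal the library
#'   barcode length.
#' @param fastq output FASTQ path (".gz" suffix gzips).
#' @param seed optional integer seed.
#' @return List: `fastq` path, `allocation` (clone x sample matrix of reads
#'   emitted per clone before sequencing error), `sheet`.
#' @export
simulate_sequencing <- function(truth, sheet, protocol, design,
                                fastq, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(protocol, "sequencing_protocol"),
            inherits(design, "barcode_design"))
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  if (anyDuplicated(sheet$index_seq)) {
    stop_ct("duplicate index sequences across samples: demultiplexing ",
            "would be ambiguous")
  }
  if (any(nchar(sheet$index_seq) != design$index_len)) {
    stop_ct("index_seq length does not match design$index_len")
  }
  L <- unique(nchar(rownames(truth$fractions)))
  if (L != design$barcode_len) {
    stop_ct("design$barcode_len (", design$barcode_len,
            ") does not match library barcode length (", L, ")")
  }
  with_seed_(seed, {
    alloc <- matrix(0L, nrow(truth$fractions), ncol(truth$fractions),
                    dimnames = dimnames(truth$fractions))
    all_reads <- vector("list", nrow(sheet))
    for (s in seq_len(nrow(sheet))) {
      reads <- simulate_sample_counts(truth$fractions[, s], protocol)
      alloc[, s] <- reads
      nz <- which(reads > 0)
      seqs <- paste0(sheet$index_seq[s], design$flank5,
                     rownames(truth$fractions)[nz], design$flank3)
      all_reads[[s]] <- rep(seqs, reads[nz])
    }
    reads <- unlist(all_reads, use.names = FALSE)
    if (protocol$error_rate > 0) {
      reads <- add_substitution_errors(reads, protocol$error_rate)
    }
    write_fastq(reads, fastq)
    list(fastq = fastq, allocation = alloc, sheet = sheet)
  })
}

# iid per-base substitution errors; errored bases switch to one of the
# other three bases uniformly
add_substitution_errors <- function(reads, rate) {
  if (length(reads) == 0L) return(reads)
  width <- nchar(reads[[1L]])
  k <- stats::rbinom(length(reads), width, rate)
  for (i in which(k > 0L)) {
    pos <- sample.int(width, k[i])
    r <- reads[i]
    for (p in pos) {
      old <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
    reads[i] <- r
  }
  reads
}

write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("read%07d", seq_along(reads))
  qual <- Biostrings::BStringSet(
    vapply(Biostrings::width(dss),
           function(w) strrep("F", w), character(1)))  # Q37 throughout
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
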