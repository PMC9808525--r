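#' Error-collapse and sampling-threshold policy
#'
#' Controls how raw extracted barcode tallies are cleaned: sequencing-error
#' collapse by directional Hamming clustering, a flat read floor, and an
#' optional per-genome fraction floor of one cell equivalent
#' (`1 / genomes_sampled`).
#'
#' @param d maximum Hamming distance for error collapse (default 1).
#' @param rho directional count ratio: a barcode merges into a parent only
#'   if `count(parent) >= rho * count(barcode) - 1` (default 2).
#' @param floor flat minimum read count per retained barcode (default 10).
#' @param genome_floor apply the `1 / genomes_sampled` fraction floor when
#'   the sample's genome count is known (default `TRUE`).
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(d = 1, rho = 2, floor = 10, genome_floor = TRUE) {
  stopifnot(d >= 0, rho >= 1, floor >= 0, is.logical(genome_floor))
  structure(list(d = as.integer(d), rho = rho, floor = floor,
                 genome_floor = genome_floor),
            class = "threshold_policy")
}

#' Extract the barcode from a single read
#'
#' Positional, flank-anchored extraction: the read must be at least as long
#' as the full layout, and both constant flanks must match within
#' `design$max_flank_mm` mismatches; the `barcode_len` bases between them
#' are returned. Rejections are data, not errors.
#'
#' @param read a read sequence (index still attached).
#' @param design a [barcode_design()].
#' @return List with `barcode` (string or `NA`) and `reason`
#'   (`"ok"`, `"flank_failed"` or `"length_failed"`).
#' @export
extract_barcode <- function(read, design) {
  if (nchar(read) < design$read_len) {
    return(list(barcode = NA_character_, reason = "length_failed"))
  }
  f5_start <- design$index_len + 1L
  f5_end <- design$index_len + nchar(design$flank5)
  bc_end <- f5_end + design$barcode_len
  f3_end <- bc_end + nchar(design$flank3)
  mm5 <- hamming(substr(read, f5_start, f5_end), design$flank5)
  mm3 <- hamming(substr(read, bc_end + 1L, f3_end), design$flank3)
  if (mm5 > design$max_flank_mm || mm3 > design$max_flank_mm) {
    return(list(barcode = NA_character_, reason = "flank_failed"))
  }
  list(barcode = substr(read, f5_end + 1L, bc_end), reason = "ok")
}

#' Demultiplex reads and extract barcodes
#'
#' Assigns each read to the unique sample whose index matches within
#' `design$max_index_mm` mismatches, then extracts the barcode between the
#' constant flanks. Every read ends up in exactly one tally:
#' `assigned + unassigned_index + flank_failed + length_failed = total`.
#'
#' @param fastq path to FASTQ (optionally gzipped), or a character vector of
#'   read sequences.
#' @param design a [barcode_design()].
#' @param sheet a [sample_sheet()]; indices must be pairwise separated by
#'   more than `2 * max_index_mm` mismatches or demultiplexing would be
#'   ambiguous.
#' @return List: `tallies` (per sample, named integer vector of raw barcode
#'   counts) and `stats` (`extraction_stats` list).
#' @export
demultiplex_extract <- function(fastq, design, sheet) {
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  idx_mat <- char_mat(sheet$index_seq, design$index_len)
  # ambiguity check: any two indices within 2*max_index_mm could both claim
  # a read
  if (nrow(sheet) > 1L) {
    for (i in seq_len(nrow(sheet) - 1L)) {
      dd <- hamming_to(idx_mat[, i], idx_mat[, -seq_len(i), drop = FALSE])
      if (any(dd <= 2L * design$max_index_mm)) {
        j <- which(dd <= 2L * design$max_index_mm)[1L] + i
        stop_ct("ambiguous index design: '", sheet$index_seq[i], "' and '",
                sheet$index_seq[j], "' are within ",
                2L * design$max_index_mm, " mismatches")
      }
    }
  }
  reads <- if (length(fastq) == 1L && file.exists(fastq)) {
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  } else {
    as.character(fastq)
  }
  total <- length(reads)
  long_enough <- nchar(reads) >= design$read_len
  n_length_failed <- sum(!long_enough)
  reads <- reads[long_enough]

  # vectorized index assignment
  assign_to <- rep(NA_integer_, length(reads))
  if (length(reads)) {
    rid <- char_mat(substr(reads, 1L, design$index_len), design$index_len)
    for (s in seq_len(nrow(sheet))) {
      hit <- colSums(rid != idx_mat[, s]) <= design$max_index_mm
      assign_to[hit] <- s
    }
  }
  n_unassigned <- sum(is.na(assign_to))

  # vectorized flank check on assigned reads
  f5_start <- design$index_len + 1L
  f5_end <- design$index_len + nchar(design$flank5)
  bc_end <- f5_end + design$barcode_len
  f3_end <- bc_end + nchar(design$flank3)
  keep <- !is.na(assign_to)
  reads_a <- reads[keep]
  assign_a <- assign_to[keep]
  ok <- logical(length(reads_a))
  if (length(reads_a)) {
    f5 <- char_mat(substr(reads_a, f5_start, f5_end), nchar(design$flank5))
    mm5 <- colSums(f5 != strsplit(design$flank5, "", fixed = TRUE)[[1L]])
    f3 <- char_mat(substr(reads_a, bc_end + 1L, f3_end), nchar(design$flank3))
    mm3 <- colSums(f3 != strsplit(design$flank3, "", fixed = TRUE)[[1L]])
    ok <- mm5 <= design$max_flank_mm & mm3 <= design$max_flank_mm
  }
  n_flank_failed <- sum(!ok)
  barcodes <- substr(reads_a[ok], f5_end + 1L, bc_end)
  samp <- assign_a[ok]

  tallies <- lapply(seq_len(nrow(sheet)), function(s) {
    tab <- table(barcodes[samp == s])
    stats::setNames(as.integer(tab), names(tab))
  })
  names(tallies) <- sheet$sample_id
  assigned <- vapply(tallies, sum, numeric(1))

  stats <- structure(list(
    total = total,
    assigned = assigned,
    unassigned_index = n_unassigned,
    flank_failed = n_flank_failed,
    length_failed = n_length_failed,
    collapsed_reads = NA_real_,
    threshold_removed_barcodes = NA_real_,
    threshold_removed_reads = NA_real_), class = "extraction_stats")
  stopifnot(sum(assigned) + n_unassigned + n_flank_failed +
              n_length_failed == total)
  list(tallies = tallies, stats = stats)
}

#' Collapse sequencing errors by greedy directional Hamming clustering
#'
#' Barcodes are visited in order of descending raw count (ties broken
#' lexicographically). Each barcode either founds a new clone or, if some
#' already-retained barcode `p` lies within Hamming distance `d` and has
#' raw count `>= rho * count(b) - 1`, is merged into the highest-raw-count
#' such parent (ties lexicographic). Parent eligibility and ranking use raw
#' (pre-merge) counts; merged reads accumulate into the parent's output
#' count. Total reads are conserved and the clone count never increases.
#'
#' @param counts named integer vector of raw barcode counts for one sample.
#' @param policy a [threshold_policy()] (uses `d` and `rho`).
#' @return Named integer vector of collapsed counts (retained barcodes).
#' @export
collapse_errors <- function(counts, policy = threshold_policy()) {
  if (length(counts) == 0L) return(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_ct("counts must be named by barcode")
  }
  L <- unique(nchar(names(counts)))
  if (length(L) != 1L) {
    stop_ct("barcodes of unequal length within one sample")
  }
  ord <- order(-counts, names(counts))
  bcs <- names(counts)[ord]
  cnt <- as.numeric(counts)[ord]
  n <- length(bcs)
  chars <- char_mat(bcs, L)
  ret_idx <- integer(0)               # indices (into sorted order) retained
  out <- numeric(n)                   # accumulated counts per retained idx
  for (i in seq_len(n)) {
    parent <- NA_integer_
    if (length(ret_idx)) {
      dd <- hamming_to(chars[, i], chars[, ret_idx, drop = FALSE])
      elig <- which(dd <= policy$d & cnt[ret_idx] >= policy$rho * cnt[i] - 1)
      # retained list is in (desc raw count, lex) order, so the first
      # eligible entry is the highest-raw-count parent with lex tie-break
      if (length(elig)) parent <- ret_idx[elig[1L]]
    }
    if (is.na(parent)) {
      ret_idx <- c(ret_idx, i)
      out[i] <- out[i] + cnt[i]
    } else {
      out[parent] <- out[parent] + cnt[i]
    }
  }
  res <- as.integer(out[ret_idx])
  names(res) <- bcs[ret_idx]
  stopifnot(sum(res) == sum(counts))
  res
}

#' Apply sampling thresholds to one sample's collapsed counts
#'
#' A barcode is retained iff its count is at least `policy$floor` and, when
#' the per-genome floor is on and `genomes_sampled` is known, its fraction
#' of the sample is at least `1 / genomes_sampled` (one cell equivalent).
#' An empty result is flagged, not an error.
#'
#' @param counts named integer vector of collapsed counts.
#' @param genomes_sampled genome equivalents assayed for this sample, or
#'   `NA`.
#' @param policy a [threshold_policy()].
#' @return List: `counts` (retained), `removed_barcodes`, `removed_reads`,
#'   `empty` flag.
#' @export
apply_sampling_threshold <- function(counts, genomes_sampled = NA,
                                     policy = threshold_policy()) {
  if (length(counts) == 0L) {
    return(list(counts = counts, removed_barcodes = 0L,
                removed_reads = 0L, empty = TRUE))
  }
  keep <- counts >= policy$floor
  if (policy$genome_floor && !is.na(genomes_sampled) && genomes_sampled >= 1) {
    keep <- keep & (counts / sum(counts) >= 1 / genomes_sampled)
  }
  list(counts = counts[keep],
       removed_barcodes = sum(!keep),
       removed_reads = sum(counts[!keep]),
       empty = !any(keep))
}

#' Assemble per-sample counts into a barcode x sample matrix
#'
#' @param tallies named list (by `sample_id`) of named count vectors.
#' @param sheet the [sample_sheet()]; column order follows the sheet.
#' @param stats optional `extraction_stats` to attach.
#' @param policy optional [threshold_policy()] to attach.
#' @return Integer matrix of class `counts_matrix` (rows: barcodes sorted
#'   lexicographically, all-zero rows dropped; columns: samples in sheet
#'   order) with `extraction_stats` and `threshold_policy` attributes.
#' @export
build_counts_matrix <- function(tallies, sheet, stats = NULL, policy = NULL) {
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  if (!all(sheet$sample_id %in% names(tallies))) {
    stop_ct("tallies missing sample(s): ",
            paste(setdiff(sheet$sample_id, names(tallies)), collapse = ", "))
  }
  all_bc <- sort(unique(unlist(lapply(tallies, names), use.names = FALSE)))
  m <- matrix(0L, length(all_bc), nrow(sheet),
              dimnames = list(all_bc, sheet$sample_id))
  for (s in sheet$sample_id) {
    v <- tallies[[s]]
    if (length(v)) m[names(v), s] <- as.integer(v)
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  attr(m, "extraction_stats") <- stats
  attr(m, "threshold_policy") <- policy
  class(m) <- c("counts_matrix", class(m))
  m
}

#' Call barcodes from multiplexed FASTQ to a counts matrix
#'
#' End-to-end barcode calling: demultiplex by index, extract barcodes
#' between the constant flanks, collapse sequencing errors per sample, apply
#' sampling thresholds, and assemble the counts matrix with a full
#' read-conservation ledger in its `extraction_stats` attribute.
#'
#' @param fastq FASTQ path or character vector of reads.
#' @param design a [barcode_design()].
#' @param sheet a [sample_sheet()].
#' @param policy a [threshold_policy()].
#' @return A `counts_matrix` (see [build_counts_matrix()]).
#' @export
call_barcodes <- function(fastq, design, sheet,
                          policy = threshold_policy()) {
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  dm <- demultiplex_extract(fastq, design, sheet)
  collapsed_reads <- 0
  removed_bc <- 0
  removed_reads <- 0
  tallies <- dm$tallies
  for (s in seq_along(tallies)) {
    raw <- tallies[[s]]
    col <- collapse_errors(raw, policy)
    # reads that belonged to merged (error) barcodes, now on their parents
    collapsed_reads <- collapsed_reads +
      sum(raw) - sum(raw[names(raw) %in% names(col)])
    thr <- apply_sampling_threshold(col, sheet$genomes_sampled[s], policy)
    removed_bc <- removed_bc + thr$removed_barcodes
    removed_reads <- removed_reads + thr$removed_reads
    tallies[[s]] <- thr$counts
  }
  stats <- dm$stats
  stats$collapsed_reads <- collapsed_reads
  stats$threshold_removed_barcodes <- removed_bc
  stats$threshold_removed_reads <- removed_reads
  build_counts_matrix(tallies, sheet, stats = stats, policy = policy)
}
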