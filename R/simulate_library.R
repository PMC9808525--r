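#' Generate a high-diversity barcode library
#'
#' Draws `D` distinct uniform-random DNA sequences of length `L`, modelling a
#' high-diversity lentiviral barcode library used to tag hematopoietic stem
#' and progenitor cells (HSPCs) before autologous transplantation.
#'
#' @param D library diversity: number of distinct barcodes (`D <= 4^L`).
#' @param L barcode length in nucleotides (default 35).
#' @param seed optional integer seed; a fixed seed gives a bit-identical
#'   library.
#' @return A `barcode_library` object: list with `barcodes` (character
#'   vector), `D` and `L`.
#' @examples
#' lib <- generate_library(100, L = 12, seed = 1)
#' length(lib$barcodes)
#' @export
generate_library <- function(D, L = 35, seed = NULL) {
  stopifnot(length(D) == 1L, length(L) == 1L)
  D <- as.numeric(D); L <- as.integer(L)
  if (D < 1 || L < 1) stop_ct("D and L must both be >= 1")
  if (D > 4^L) {
    stop_ct("infeasible diversity: D = ", D, " exceeds 4^L = ", 4^L)
  }
  with_seed_(seed, {
    barcodes <- character(0)
    while (length(barcodes) < D) {
      need <- D - length(barcodes)
      # oversample to absorb duplicates when D is close to 4^L
      n_draw <- max(need, ceiling(need * 1.2) + 8L)
      draw <- matrix(sample(DNA_BASES, n_draw * L, replace = TRUE), ncol = L)
      new <- unique(do.call(paste0, as.data.frame(draw, stringsAsFactors = FALSE)))
      new <- setdiff(new, barcodes)
      barcodes <- c(barcodes, new[seq_len(min(need, length(new)))])
    }
    barcode_library(barcodes)
  })
}

#' Construct a barcode library from explicit sequences
#'
#' @param barcodes character vector of equal-length, distinct ACGT strings.
#' @return A `barcode_library` object.
#' @export
barcode_library <- function(barcodes) {
  barcodes <- as.character(barcodes)
  if (length(barcodes) < 1L) stop_ct("library must contain at least one barcode")
  L <- unique(nchar(barcodes))
  if (length(L) != 1L) stop_ct("all barcodes must have the same length")
  if (anyDuplicated(barcodes)) stop_ct("library barcodes must be distinct")
  if (any(grepl("[^ACGT]", barcodes))) stop_ct("barcodes restricted to ACGT")
  structure(list(barcodes = barcodes, D = length(barcodes), L = L),
            class = "barcode_library")
}

#' Probability that a transduced cell carries a unique barcode
#'
#' Under uniform barcode assignment with replacement from a library of
#' diversity `D`, the probability that a given transduced cell among `k`
#' shares its barcode with none of the other `k - 1` cells is
#' `(1 - 1/D)^(k-1)`. Libraries for HSPC clonal tracking are designed so
#' this exceeds 0.95, making each engrafted clone identifiable by a single
#' barcode.
#'
#' @param D library diversity (number of distinct barcodes).
#' @param k number of transduced cells.
#' @return Probability in `[0, 1]`.
#' @examples
#' unique_labeling_probability(1e7, 5e5)
#' @export
unique_labeling_probability <- function(D, k) {
  stopifnot(D >= 1, k >= 1)
  (1 - 1 / D)^(k - 1)
}

#' Simulate lentiviral transduction of HSPCs
#'
#' Assigns each of `k` cells a barcode drawn uniformly with replacement from
#' the library, and flags cells whose barcode is shared with another cell
#' (barcode collision, which makes two clones indistinguishable).
#'
#' @param library a [barcode_library()] object, or a single number taken as
#'   the diversity `D` (barcodes then not materialized; useful for collision
#'   Monte-Carlo at very large `D`).
#' @param k number of transduced cells (`k >= 1`).
#' @param seed optional integer seed.
#' @return A `clone_assignment` object: list with `cell_barcode` (character,
#'   or integer library indices in diversity-only mode), `collided` (logical
#'   per cell) and `unique_fraction` (empirical fraction of uniquely labeled
#'   cells).
#' @export
simulate_transduction <- function(library, k, seed = NULL) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  with_seed_(seed, {
    if (inherits(library, "barcode_library")) {
      idx <- sample.int(library$D, k, replace = TRUE)
      cell_barcode <- library$barcodes[idx]
    } else {
      D <- as.numeric(library)
      stopifnot(length(D) == 1L, D >= 1)
      idx <- sample.int(D, k, replace = TRUE)
      cell_barcode <- idx
    }
    collided <- duplicated(idx) | duplicated(idx, fromLast = TRUE)
    structure(list(cell_barcode = cell_barcode,
                   collided = collided,
                   unique_fraction = 1 - mean(collided)),
              class = "clone_assignment")
  })
}

#' Generate mutually distant sample index sequences
#'
#' Greedy random search for `n` index sequences of length `len` whose
#' pairwise Hamming distance is at least `min_dist`, so that demultiplexing
#' with up to `floor((min_dist - 1) / 2)` mismatches is unambiguous.
#'
#' @param n number of indices.
#' @param len index length (default 8).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param seed optional integer seed.
#' @return Character vector of `n` index sequences.
#' @export
generate_indices <- function(n, len = 8, min_dist = 3, seed = NULL) {
  stopifnot(n >= 1, len >= 1, min_dist >= 1)
  with_seed_(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      ok <- TRUE
      if (length(out) > 0L) {
        ok <- all(hamming_to(strsplit(cand, "", fixed = TRUE)[[1L]],
                             char_mat(out, len)) >= min_dist)
      }
      if (ok) out <- c(out, cand)
      tries <- tries + 1L
      if (tries > 10000L * n) {
        stop_ct("could not find ", n, " indices at pairwise distance >= ",
                min_dist, "; increase len or lower min_dist")
      }
    }
    out
  })
}
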