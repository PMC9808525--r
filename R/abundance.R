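new_abundance <- function(m, repr, log_floor = NULL, empty = character(0)) {
  attr(m, "repr") <- repr
  attr(m, "log_floor") <- log_floor
  attr(m, "empty_samples") <- empty
  class(m) <- c("abundance_matrix", "matrix", "array")
  m
}

#' Fractional abundance of each clone per sample
#'
#' Each barcode's read count divided by its sample's total retained reads:
#' the clone's fractional contribution to that sample. Empty (all-zero)
#' samples are dropped and recorded in the `empty_samples` attribute.
#'
#' @param counts a `counts_matrix` (or plain nonnegative matrix).
#' @return An `abundance_matrix` with `repr = "fraction"`; every retained
#'   column sums to 1.
#' @export
to_fractional_abundance <- function(counts) {
  m <- unclass(counts)
  if (any(m < 0)) stop_ct("counts must be nonnegative")
  tot <- colSums(m)
  if (all(tot == 0)) stop_ct("all samples are empty; no abundances to compute")
  empty <- colnames(m)[tot == 0] %||% character(0)
  m <- m[, tot > 0, drop = FALSE]
  f <- sweep(m, 2, colSums(m), "/")
  new_abundance(f, "fraction", empty = empty)
}

#' Counts-per-million normalization
#'
#' Fractional abundance scaled by `1e6`, the scale conventionally used for
#' sample-level ordination of clone contributions.
#'
#' @inheritParams to_fractional_abundance
#' @return An `abundance_matrix` with `repr = "cpm"`; columns sum to `1e6`.
#' @export
to_cpm <- function(counts) {
  f <- to_fractional_abundance(counts)
  new_abundance(unclass(f) * 1e6, "cpm",
                empty = attr(f, "empty_samples"))
}

#' Natural-log fractional abundance
#'
#' Entrywise `log()` of a fraction matrix, the representation used for
#' top-clone heat maps. Zeros (clones absent from a sample) are replaced by
#' `log(floor)` where the floor is half the smallest nonzero fraction in the
#' matrix (default) or a fixed pseudo-fraction; the floor used is recorded
#' in the `log_floor` attribute.
#'
#' @param fractions an `abundance_matrix` with `repr = "fraction"` (or plain
#'   matrix of fractions).
#' @param floor_strategy `"half_min"` (default) or `"fixed"`.
#' @param pseudo_fraction fixed floor when `floor_strategy = "fixed"`.
#' @return An `abundance_matrix` with `repr = "log_fraction"`; all entries
#'   `<= 0`.
#' @export
log_fractional_abundance <- function(fractions,
                                     floor_strategy = c("half_min", "fixed"),
                                     pseudo_fraction = NULL) {
  floor_strategy <- match.arg(floor_strategy)
  m <- unclass(fractions)
  repr <- attr(fractions, "repr")
  if (!is.null(repr) && repr != "fraction") {
    stop_ct("log_fractional_abundance needs a fraction matrix, got repr='",
            repr, "'")
  }
  if (any(m < 0)) stop_ct("fractions must be nonnegative")
  if (any(m > 1 + 1e-9)) stop_ct("fractions must not exceed 1")
  floor_val <- if (floor_strategy == "half_min") {
    nz <- m[m > 0]
    if (!length(nz)) stop_ct("matrix has no nonzero fractions")
    min(nz) / 2
  } else {
    if (is.null(pseudo_fraction) || pseudo_fraction <= 0) {
      stop_ct("floor_strategy='fixed' needs a positive pseudo_fraction")
    }
    pseudo_fraction
  }
  out <- log(pmax(m, floor_val))
  new_abundance(out, "log_fraction", log_floor = floor_val,
                empty = attr(fractions, "empty_samples") %||% character(0))
}
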