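DNA_BASES <- c("A", "C", "G", "T")

# default read architecture: 8 nt i5-style index, 20 nt constant flanks
DEFAULT_FLANK5 <- "ACTGCGTCAGGTACCTAGCG"
DEFAULT_FLANK3 <- "GATCCTGGAACGTCAGTGCA"

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Split equal-length strings into a character matrix (one column per string)
#' @noRd
char_mat <- function(x, width = NULL) {
  if (length(x) == 0L) {
    return(matrix(character(0), nrow = if (is.null(width)) 0L else width))
  }
  if (is.null(width)) width <- nchar(x[[1L]])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = width)
}

#' Hamming distances from one string to a column-wise character matrix
#' @noRd
hamming_to <- function(chars, mat) {
  if (ncol(mat) == 0L) return(integer(0))
  colSums(mat != chars)
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Largest-remainder integer allocation of `total` units over weights `w`
#'
#' Deterministic: remainder ties broken by index. Used by the noise-free
#' sequencing path so exact fraction recovery holds up to integer rounding.
#' @noRd
lr_alloc <- function(w, total) {
  stopifnot(all(w >= 0), total >= 0)
  if (sum(w) == 0) return(integer(length(w)))
  p <- w / sum(w)
  raw <- p * total
  base <- floor(raw)
  extra <- round(total - sum(base))
  if (extra > 0) {
    ord <- order(-(raw - base), seq_along(w))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ct <- function(...) stop(..., call. = FALSE)
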