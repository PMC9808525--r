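pkg_version <- function() {
  as.character(utils::packageVersion("clonaltracker"))
}

prov_lines <- function(config_hash = NULL, extra = NULL) {
  c(paste0("clonaltracker ", pkg_version(),
           if (!is.null(config_hash)) paste0(" config=", config_hash)),
    extra)
}

#' Write a counts matrix to TSV
#'
#' First column `barcode`, one column per sample; optional `# ` provenance
#' header lines.
#'
#' @param counts a `counts_matrix` or plain matrix with dimnames.
#' @param path output path.
#' @param provenance optional header lines (without the `# `).
#' @return `path`, invisibly.
#' @export
write_counts_matrix <- function(counts, path, provenance = NULL) {
  m <- unclass(counts)
  df <- data.frame(barcode = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_prov(df, path, provenance)
}

#' Read a counts matrix from TSV
#' @param path TSV written by [write_counts_matrix()].
#' @return Integer matrix of class `counts_matrix`.
#' @export
read_counts_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$barcode
  class(m) <- c("counts_matrix", class(m))
  m
}

#' Write an abundance matrix to TSV
#'
#' The representation tag is stored in a `#repr=` header line (plus
#' `#log_floor=` for log matrices) so a reader can recover it.
#'
#' @param ab an `abundance_matrix`.
#' @param path output path.
#' @param provenance optional extra header lines.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(ab, path, provenance = NULL) {
  m <- unclass(ab)
  hdr <- c(provenance, paste0("repr=", attr(ab, "repr") %||% "fraction"))
  lf <- attr(ab, "log_floor")
  if (!is.null(lf)) hdr <- c(hdr, sprintf("log_floor=%.17g", lf))
  df <- data.frame(barcode = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_prov(df, path, hdr)
}

#' Read an abundance matrix from TSV
#' @param path TSV written by [write_abundance()].
#' @return An `abundance_matrix` with its representation tag restored.
#' @export
read_abundance <- function(path) {
  head_lines <- readLines(path, n = 50)
  head_lines <- head_lines[startsWith(head_lines, "# ")]
  repr <- sub("^# repr=", "", grep("^# repr=", head_lines, value = TRUE))
  lf <- sub("^# log_floor=", "",
            grep("^# log_floor=", head_lines, value = TRUE))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode
  new_abundance(m, if (length(repr)) repr[1] else "fraction",
                log_floor = if (length(lf)) as.numeric(lf[1]) else NULL)
}

#' Write simulation ground truth
#'
#' Clone x sample true fractions as TSV plus a JSON sidecar carrying the
#' seed and planted biases.
#'
#' @param truth a `simulation_truth`.
#' @param tsv,json output paths.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(truth, tsv, json) {
  df <- data.frame(barcode = rownames(truth$fractions), truth$fractions,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_prov(df, tsv, prov_lines())
  side <- list(seed = truth$seed,
               n_clones = length(truth$clone_barcodes),
               biased = truth$biased)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(tsv, json))
}

#' Read simulation ground-truth fractions
#' @param tsv path written by [write_truth()].
#' @return Clone x sample fraction matrix.
#' @export
read_truth_fractions <- function(tsv) {
  df <- utils::read.delim(tsv, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode
  m
}
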