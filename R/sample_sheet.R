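TISSUES <- c("PB", "liver", "spleen", "jejunum", "colon", "BAL", "LN")
POPULATIONS <- c("T", "B", "Gr", "Mono",
                 "NK_CD16", "NK_CD56", "NK_DN", "NK_bulk")

SHEET_COLS <- c("sample_id", "animal", "tissue", "population",
                "timepoint_months", "index_seq", "genomes_sampled")

vocab_ok <- function(x, vocab) x %in% vocab | grepl("^other:.+", x)

#' Build a sample sheet
#'
#' A sample sheet describes every sequenced cell sample: which animal,
#' tissue and sorted immune population it came from, the timepoint in months
#' post-transplantation, the sample's demultiplexing index sequence, and
#' (optionally) the number of cell genome equivalents that went into the
#' barcode PCR, which sets the sampling-depth detection floor.
#'
#' Tissues are drawn from `PB, liver, spleen, jejunum, colon, BAL, LN` and
#' populations from `T, B, Gr, Mono, NK_CD16, NK_CD56, NK_DN, NK_bulk`;
#' other labels must be written `other:<label>`.
#'
#' @param sample_id unique sample identifiers.
#' @param animal animal identifier(s).
#' @param tissue tissue of origin per sample.
#' @param population sorted cell population per sample.
#' @param timepoint_months months post-transplantation (`>= 0`).
#' @param index_seq unique per-sample index sequences (uniform length).
#' @param genomes_sampled genome equivalents assayed, or `NA`.
#' @return A validated `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, animal, tissue, population,
                         timepoint_months, index_seq,
                         genomes_sampled = NA_real_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   animal = as.character(animal),
                   tissue = as.character(tissue),
                   population = as.character(population),
                   timepoint_months = as.numeric(timepoint_months),
                   index_seq = as.character(index_seq),
                   genomes_sampled = as.numeric(genomes_sampled),
                   stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet, reporting all violations at once
#'
#' @param df data.frame with the sample-sheet columns.
#' @return The sheet with class `sample_sheet`; errors aggregate every
#'   violation with its row number.
#' @export
validate_sample_sheet <- function(df) {
  errs <- character(0)
  missing <- setdiff(SHEET_COLS, names(df))
  if (length(missing)) {
    stop_ct("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  }
  line <- function(i) paste0("line ", paste(i, collapse = ","))
  dup <- df$sample_id[duplicated(df$sample_id)]
  for (d in unique(dup)) {
    errs <- c(errs, paste0("duplicate sample_id '", d, "' (",
                           line(which(df$sample_id == d)), ")"))
  }
  dupi <- df$index_seq[duplicated(df$index_seq)]
  for (d in unique(dupi)) {
    errs <- c(errs, paste0("duplicate index_seq '", d, "' (",
                           line(which(df$index_seq == d)), ")"))
  }
  if (length(unique(nchar(df$index_seq))) > 1L) {
    errs <- c(errs, "index_seq lengths are not uniform")
  }
  bad <- which(!vocab_ok(df$tissue, TISSUES))
  for (i in bad) {
    errs <- c(errs, paste0("unknown tissue '", df$tissue[i], "' (", line(i),
                           "); use one of ", paste(TISSUES, collapse = "/"),
                           " or 'other:<label>'"))
  }
  bad <- which(!vocab_ok(df$population, POPULATIONS))
  for (i in bad) {
    errs <- c(errs, paste0("unknown population '", df$population[i], "' (",
                           line(i), "); use one of ",
                           paste(POPULATIONS, collapse = "/"),
                           " or 'other:<label>'"))
  }
  tp <- suppressWarnings(as.numeric(df$timepoint_months))
  bad <- which(is.na(tp) | tp < 0)
  for (i in bad) {
    errs <- c(errs, paste0("malformed timepoint_months '",
                           df$timepoint_months[i], "' (", line(i), ")"))
  }
  if (length(errs)) {
    stop_ct("invalid sample sheet:\n  - ", paste(errs, collapse = "\n  - "))
  }
  df$timepoint_months <- tp
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from TSV
#' @param path TSV file with the sample-sheet header.
#' @return A validated `sample_sheet`.
#' @export
load_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  df$timepoint_months <- as.numeric(df$timepoint_months)
  df$genomes_sampled <- suppressWarnings(as.numeric(df$genomes_sampled))
  validate_sample_sheet(df)
}

#' Write a sample sheet to TSV
#' @param sheet a `sample_sheet`.
#' @param path output path.
#' @param provenance optional provenance header lines (without "#").
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path, provenance = NULL) {
  write_tsv_prov(as.data.frame(sheet), path, provenance)
}

# shared TSV writer: optional "# ..." provenance lines, then header + rows
write_tsv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
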