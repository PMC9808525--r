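loc_label <- function(tissue, population) paste(tissue, population, sep = ":")

#' Average clonal contributions across timepoints per location
#'
#' For every location (tissue x population), the clone-wise arithmetic mean
#' of fractional abundances over that location's sampled timepoints; a clone
#' absent at a timepoint contributes 0 to its mean. Locations sampled once
#' pass through unchanged.
#'
#' @param fractions clone x sample fraction matrix (columns named by
#'   `sample_id`).
#' @param sheet the [sample_sheet()] describing those samples.
#' @return Clone x location matrix; columns labeled `tissue:population` in
#'   first-appearance order.
#' @export
timepoint_average <- function(fractions, sheet) {
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  m <- unclass(fractions)
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing)) {
    stop_ct("samples absent from sheet: ", paste(missing, collapse = ", "))
  }
  sheet <- sheet[match(colnames(m), sheet$sample_id), ]
  grp <- loc_label(sheet$tissue, sheet$population)
  groups <- unique(grp)
  out <- matrix(0, nrow(m), length(groups),
                dimnames = list(rownames(m), groups))
  for (g in groups) {
    cols <- which(grp == g)
    if (!length(cols)) stop_ct("empty group: ", g)
    out[, g] <- rowMeans(m[, cols, drop = FALSE])
  }
  out
}

#' Top-N contributing clones per sample
#'
#' The N largest-fraction barcodes of each sample (ties broken
#' lexicographically by barcode), the union of those sets across samples
#' (the heat-map row set), and a star matrix flagging, for each union clone
#' and sample, whether the clone is in that sample's top N.
#'
#' @param fractions clone x sample fraction (or averaged-fraction) matrix.
#' @param n set size per sample (default 10).
#' @return List: `top` (named list of ranked barcode vectors per sample),
#'   `union` (sorted barcode vector), `star` (logical union x sample
#'   matrix).
#' @export
top_clones <- function(fractions, n = 10) {
  stopifnot(n >= 1)
  m <- unclass(fractions)
  top <- lapply(seq_len(ncol(m)), function(s) {
    ord <- order(-m[, s], rownames(m))
    rownames(m)[ord[seq_len(min(n, nrow(m)))]]
  })
  names(top) <- colnames(m)
  un <- sort(unique(unlist(top, use.names = FALSE)))
  star <- matrix(FALSE, length(un), ncol(m), dimnames = list(un, colnames(m)))
  for (s in seq_along(top)) star[top[[s]], s] <- TRUE
  list(top = top, union = un, star = star)
}

#' Detect tissue-biased clonal expansions
#'
#' A clone is called biased toward a focal location when its
#' (timepoint-averaged) fractional abundance there exceeds `threshold`
#' times its abundance in every other location:
#' `fold = focal / max(epsilon, competing)` with `competing` the max
#' (default) or mean over the other locations. `epsilon` guards zero
#' denominators and is recorded in each call; by default it is the smallest
#' representable fraction in the dataset, one read in the deepest sample
#' (`1 / max(colSums(counts))`) when `counts` is supplied, else the smallest
#' nonzero averaged fraction.
#'
#' Screening is restricted by default to clones that are a top-`top_n`
#' clone in at least one location (`screen = "all"` extends to every
#' clone).
#'
#' @param averaged clone x location matrix from [timepoint_average()]
#'   (needs >= 2 locations).
#' @param threshold fold threshold (default 5; calls require
#'   `fold > threshold`).
#' @param compare `"max"` (default: expanded versus every other location)
#'   or `"mean"`.
#' @param epsilon explicit zero-denominator guard, or `NULL` to derive it.
#' @param counts optional `counts_matrix` used to derive `epsilon`.
#' @param screen `"top"` (default) or `"all"`.
#' @param top_n top-set size used when `screen = "top"`.
#' @return `data.frame` of calls: `barcode`, `location`, `focal_fraction`,
#'   `competing_fraction`, `fold`, `epsilon`.
#' @export
detect_biased_clones <- function(averaged, threshold = 5,
                                 compare = c("max", "mean"),
                                 epsilon = NULL, counts = NULL,
                                 screen = c("top", "all"), top_n = 10) {
  compare <- match.arg(compare)
  screen <- match.arg(screen)
  m <- unclass(averaged)
  if (ncol(m) < 2L) {
    stop_ct("biased-clone detection needs at least 2 locations")
  }
  if (is.null(epsilon)) {
    epsilon <- if (!is.null(counts)) {
      1 / max(colSums(unclass(counts)))
    } else {
      nz <- m[m > 0]
      if (!length(nz)) stop_ct("no nonzero fractions to derive epsilon from")
      min(nz)
    }
  }
  cand <- if (screen == "top") top_clones(m, top_n)$union else rownames(m)
  calls <- list()
  for (b in cand) {
    for (l in colnames(m)) {
      focal <- m[b, l]
      if (focal <= 0) next
      others <- m[b, setdiff(colnames(m), l)]
      competing <- if (compare == "max") max(others) else mean(others)
      fold <- focal / max(epsilon, competing)
      if (fold > threshold) {
        calls[[length(calls) + 1L]] <- data.frame(
          barcode = b, location = l, focal_fraction = focal,
          competing_fraction = competing, fold = fold, epsilon = epsilon,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(barcode = character(0), location = character(0),
                      focal_fraction = numeric(0),
                      competing_fraction = numeric(0),
                      fold = numeric(0), epsilon = numeric(0)))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Aggregate contribution of one population's top clones everywhere else
#'
#' Ranks the index location's clones by mean fraction over its timepoints,
#' takes the top `n`, and reports the summed fraction those clones make up
#' in every location (per timepoint, then averaged over each location's
#' timepoints). The self-contribution is included.
#'
#' @param fractions clone x sample fraction matrix.
#' @param sheet the [sample_sheet()].
#' @param index_tissue,index_population the index location.
#' @param n top-set size (default 10).
#' @return List: `index` (location label), `top_barcodes`, `contributions`
#'   (`data.frame(location, contribution)` with self first; contributions in
#'   `[0, 1]`).
#' @export
aggregate_top_contribution <- function(fractions, sheet, index_tissue,
                                       index_population, n = 10) {
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  avg <- timepoint_average(fractions, sheet)
  index <- loc_label(index_tissue, index_population)
  if (!index %in% colnames(avg)) {
    stop_ct("unknown index population: ", index)
  }
  ord <- order(-avg[, index], rownames(avg))
  top_bc <- rownames(avg)[ord[seq_len(min(n, nrow(avg)))]]
  top_bc <- top_bc[avg[top_bc, index] > 0]
  contrib <- colSums(avg[top_bc, , drop = FALSE])
  locs <- c(index, setdiff(colnames(avg), index))
  list(index = index,
       top_barcodes = top_bc,
       contributions = data.frame(location = locs,
                                  contribution = unname(contrib[locs]),
                                  stringsAsFactors = FALSE))
}

#' Clone sharing between two sample groups
#'
#' A clone is present in a group when its mean fraction over the group's
#' samples is positive and at least `floor`. Reports shared / group-only
#' clone counts, the Jaccard index, and the mass (summed mean fraction)
#' that shared clones carry in each group.
#'
#' @param fractions clone x sample fraction matrix.
#' @param group_a,group_b disjoint vectors of sample ids (columns of
#'   `fractions`).
#' @param floor presence floor on the mean fraction (default 0: any
#'   positive mean counts).
#' @return List: `shared`, `a_only`, `b_only` (clone counts), `jaccard`,
#'   `shared_mass_a`, `shared_mass_b`, `shared_barcodes`.
#' @export
shared_clone_summary <- function(fractions, group_a, group_b, floor = 0) {
  m <- unclass(fractions)
  stopifnot(all(group_a %in% colnames(m)), all(group_b %in% colnames(m)))
  if (length(intersect(group_a, group_b))) {
    stop_ct("groups must be disjoint")
  }
  mean_a <- rowMeans(m[, group_a, drop = FALSE])
  mean_b <- rowMeans(m[, group_b, drop = FALSE])
  in_a <- mean_a > 0 & mean_a >= floor
  in_b <- mean_b > 0 & mean_b >= floor
  shared <- in_a & in_b
  un <- in_a | in_b
  list(shared = sum(shared),
       a_only = sum(in_a & !in_b),
       b_only = sum(in_b & !in_a),
       jaccard = if (sum(un) == 0) NA_real_ else sum(shared) / sum(un),
       shared_mass_a = sum(mean_a[shared]),
       shared_mass_b = sum(mean_b[shared]),
       shared_barcodes = rownames(m)[shared])
}
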