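#' Hierarchical clustering of clone rows (or samples)
#'
#' Agglomerative clustering of Euclidean distances between rows, as used to
#' order top-clone log-abundance heat maps. Rows are pre-sorted
#' lexicographically by label so tied merges resolve deterministically.
#'
#' @param x numeric matrix with finite entries (zeros already log-floored)
#'   and >= 2 rows; rownames required.
#' @param linkage one of `"complete"` (default), `"average"`, `"single"`,
#'   `"ward.D2"`.
#' @return List: `hclust` object, `order` (row labels in dendrogram order),
#'   `dist` (the distance matrix, as `dist`), `linkage`.
#' @export
cluster_rows <- function(x, linkage = c("complete", "average", "single",
                                        "ward.D2")) {
  linkage <- match.arg(linkage)
  m <- unclass(x)
  if (nrow(m) < 2L) stop_ct("clustering needs at least 2 rows")
  if (is.null(rownames(m))) stop_ct("rows must be labeled")
  if (!all(is.finite(m))) stop_ct("non-finite values in input")
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = hc$labels[hc$order], dist = d, linkage = linkage)
}

#' Write a dendrogram as newick
#' @param clust result of [cluster_rows()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clust, path) {
  ape::write.tree(ape::as.phylo(clust$hclust), file = path)
  invisible(path)
}

#' Project samples onto principal components of their clone profiles
#'
#' Clone-wise centered (optionally unit-variance scaled) PCA of a
#' clone x sample matrix, projecting samples into a low-dimensional space
#' where proximity reflects similarity of clonal composition. Component
#' signs are fixed by forcing the largest-magnitude loading of each
#' component positive.
#'
#' @param x clone x sample numeric matrix (typically CPM); >= 2 samples and
#'   `n_components < min(samples, clones)`.
#' @param n_components number of components to return (default 2).
#' @param scale. unit-variance scale clones before projection (default
#'   `FALSE`).
#' @return List: `coords` (sample x component scores), `var_explained`
#'   (fraction per returned component), `center`, `rotation`.
#' @export
pca_project <- function(x, n_components = 2, scale. = FALSE) {
  m <- unclass(x)
  n_samp <- ncol(m)
  if (n_samp < 2L) stop_ct("PCA needs at least 2 samples")
  if (n_components >= min(n_samp, nrow(m))) {
    stop_ct("n_components must be < min(samples, clones)")
  }
  if (scale.) {
    sds <- apply(m, 1, stats::sd)
    m <- m[sds > 0, , drop = FALSE]
  }
  p <- stats::prcomp(t(m), center = TRUE, scale. = scale.)
  k <- seq_len(n_components)
  rot <- p$rotation[, k, drop = FALSE]
  sco <- p$x[, k, drop = FALSE]
  for (j in k) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(coords = sco,
       var_explained = (p$sdev^2 / sum(p$sdev^2))[k],
       center = p$center,
       rotation = rot)
}

#' Pairwise Pearson correlation of samples' clonal contributions
#'
#' Pearson r between every pair of samples over the union of all retrieved
#' clones (absent clones count as 0), on linear fractional abundances by
#' default or natural-log abundances.
#'
#' @param x clone x sample matrix (>= 2 samples).
#' @param scale `"linear"` (default) or `"log"` (log with half-min zero
#'   floor applied first).
#' @return Sample x sample correlation matrix; symmetric, unit diagonal.
#'   Samples with zero variance across clones yield `NA` rows/columns with
#'   a warning (their diagonal stays 1).
#' @export
pearson_pairwise <- function(x, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  m <- unclass(x)
  if (ncol(m) < 2L) stop_ct("correlation needs at least 2 samples")
  if (scale == "log") {
    m <- unclass(log_fractional_abundance(m))
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance sample(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; their correlations are reported as NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}
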