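# Independent brute-force oracles and small fixture builders. Oracles are
# written naively (explicit loops, textbook formulas) so they share no code
# with the implementation paths they check.

oracle_hamming <- function(a, b) {
  sum(mapply(function(x, y) x != y,
             strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
}

# directional error collapse by exhaustive candidate-parent enumeration
oracle_collapse <- function(counts, d, rho) {
  ord <- order(-counts, names(counts))
  bcs <- names(counts)[ord]
  cnt <- as.numeric(counts)[ord]
  retained <- character(0)
  raw <- numeric(0)
  out <- numeric(0)
  for (i in seq_along(bcs)) {
    cand <- character(0)
    for (r in retained) {
      if (oracle_hamming(r, bcs[i]) <= d && raw[r] >= rho * cnt[i] - 1) {
        cand <- c(cand, r)
      }
    }
    if (length(cand) == 0) {
      retained <- c(retained, bcs[i])
      raw[bcs[i]] <- cnt[i]
      out[bcs[i]] <- cnt[i]
    } else {
      best <- cand[order(-raw[cand], cand)][1]
      out[best] <- out[best] + cnt[i]
    }
  }
  res <- as.integer(out[retained])
  names(res) <- retained
  res
}

# naive complete-linkage agglomeration; returns merge heights in order
oracle_complete_linkage_heights <- function(m) {
  d0 <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- max(d0[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# textbook Pearson r: cov / (sd * sd), computed elementwise
oracle_pearson <- function(x) {
  n <- ncol(x)
  r <- matrix(NA_real_, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- x[, i]; b <- x[, j]
      cov_ab <- sum((a - mean(a)) * (b - mean(b))) / (length(a) - 1)
      r[i, j] <- cov_ab / (stats::sd(a) * stats::sd(b))
    }
  }
  r
}

# PCA scores by direct eigendecomposition of the sample covariance
oracle_pca_scores <- function(x, k) {
  X <- t(x)
  Xc <- sweep(X, 2, colMeans(X))
  ee <- eigen(stats::cov(Xc), symmetric = TRUE)
  Xc %*% ee$vectors[, seq_len(k), drop = FALSE]
}

random_barcodes <- function(n, L) {
  replicate(n, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = ""))
}

# small 2-tissue x 1-population x 2-timepoint sheet
tiny_sheet <- function(tissues = c("PB", "liver"), populations = "T",
                       timepoints = c(12, 14), genomes = 5e4, seed = 11) {
  grid <- expand.grid(tissue = tissues, population = populations,
                      timepoint = timepoints, stringsAsFactors = FALSE)
  sample_sheet(
    sample_id = sprintf("%s_%s_%dm", grid$tissue, grid$population,
                        grid$timepoint),
    animal = "SIM01",
    tissue = grid$tissue,
    population = grid$population,
    timepoint_months = grid$timepoint,
    index_seq = generate_indices(nrow(grid), len = 8, min_dist = 3,
                                 seed = seed),
    genomes_sampled = genomes)
}

# fraction matrix with named dims from a plain numeric matrix
frac_mat <- function(m, barcodes = NULL, samples = NULL) {
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(barcodes, samples)
  m
}
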