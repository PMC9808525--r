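test_that("row clustering merges identical rows first and matches the oracle", {
  m <- matrix(c(0, 0, 0,
                0, 0, 0,
                3, 4, 5,
                9, 9, 9), nrow = 4, byrow = TRUE,
              dimnames = list(c("b1", "b2", "b3", "b4"), NULL))
  cl <- cluster_rows(m)
  expect_equal(cl$hclust$height[1], 0)   # identical rows merge at 0
  dm <- as.matrix(cl$dist)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  first <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_identical(first, c("b1", "b2"))
  for (i in 1:10) {
    withr::with_seed(500 + i, {
      r <- matrix(rnorm(5 * 7), 5, 7,
                  dimnames = list(sprintf("c%d", 1:5), NULL))
      got <- cluster_rows(r)$hclust$height
      expect_equal(got, oracle_complete_linkage_heights(
        r[order(rownames(r)), ]), tolerance = 1e-9)
    })
  }
  expect_error(cluster_rows(m[1, , drop = FALSE]), "2 rows")
  m_bad <- m
  m_bad[1, 1] <- NA
  expect_error(cluster_rows(m_bad), "finite")
})

test_that("PCA projection is centered, ordered and sign-stable", {
  withr::with_seed(77, {
    x <- matrix(rnorm(8 * 6), 8, 6,
                dimnames = list(sprintf("B%d", 1:8), sprintf("s%d", 1:6)))
  })
  p <- pca_project(x, n_components = 2)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  want <- oracle_pca_scores(x, 2)
  expect_equal(abs(unname(p$coords)), abs(unname(want)), tolerance = 1e-9)
  # duplicated sample projects to identical coordinates
  x2 <- cbind(x, s7 = x[, 1])
  p2 <- pca_project(x2, 2)
  expect_equal(p2$coords["s1", ], p2$coords["s7", ])
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) {
    expect_gt(p$rotation[which.max(abs(p$rotation[, j])), j], 0)
  }
  # clone row order leaves coordinates unchanged (up to nothing: exact)
  perm <- pca_project(x[sample(8), ], 2)
  expect_equal(abs(unname(perm$coords)), abs(unname(p$coords)),
               tolerance = 1e-9)
  expect_error(pca_project(x[, 1, drop = FALSE]), "2 samples")
  expect_error(pca_project(x, 6), "n_components")
})

test_that("pairwise Pearson matches the covariance formula", {
  f <- frac_mat(matrix(c(0.9, 0.1, 0.1, 0.9), ncol = 2))
  r <- pearson_pairwise(f)
  expect_equal(unname(diag(r)), c(1, 1))
  expect_equal(r[1, 2], -1)
  withr::with_seed(41, {
    x <- matrix(runif(30 * 5), 30, 5,
                dimnames = list(sprintf("B%d", 1:30), sprintf("s%d", 1:5)))
    x <- sweep(x, 2, colSums(x), "/")
  })
  got <- pearson_pairwise(x)
  want <- oracle_pearson(x)
  diag(want) <- 1
  expect_equal(got, want, tolerance = 1e-9)
  expect_true(isSymmetric(got))
  # column order invariance (up to permutation)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(pearson_pairwise(x[, perm])[colnames(x), colnames(x)], got)
  flat <- cbind(x, s6 = rep(1 / 30, 30))
  expect_warning(rf <- pearson_pairwise(flat), "zero-variance")
  expect_true(all(is.na(rf["s6", setdiff(colnames(flat), "s6")])))
  expect_equal(rf["s6", "s6"], 1)
})

test_that("same-tissue samples correlate more than cross-tissue ones", {
  sheet <- tiny_sheet(tissues = c("PB", "liver", "jejunum"))
  asn <- simulate_transduction(generate_library(2000, 35, seed = 61), 300,
                               seed = 62)
  bias <- data.frame(baseline_rank = c(12, 15, 18, 21),
                     tissue = rep(c("liver", "jejunum"), 2), fold = 10)
  tr <- simulate_clonal_dynamics(
    asn, dynamics_config(150, temporal_sigma = 0.1, tissue_bias = bias),
    sheet, seed = 63)
  r <- pearson_pairwise(tr$fractions)
  tis <- sheet$tissue[match(colnames(r), sheet$sample_id)]
  same <- outer(tis, tis, `==`) & upper.tri(r)
  diff_t <- outer(tis, tis, `!=`) & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff_t]))
})
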