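test_that("timepoint averaging is clone-wise and mass-preserving", {
  sheet <- tiny_sheet()  # samples: PB 12m, liver 12m, PB 14m, liver 14m
  f <- frac_mat(matrix(c(0.2, 0.8, 0.5, 0.5, 0.0, 1.0, 0.4, 0.6), nrow = 2),
                samples = sheet$sample_id)
  avg <- timepoint_average(f, sheet)
  expect_identical(colnames(avg), c("PB:T", "liver:T"))
  # clone present at 0.2 and 0.0 across the two PB timepoints
  expect_equal(unname(avg[1, "PB:T"]), 0.1)
  expect_true(all(abs(colSums(avg) - 1) < 1e-12))
  one <- timepoint_average(f[, 1, drop = FALSE], sheet[1, ])
  expect_equal(unname(one[, 1]), unname(f[, 1]))
  expect_error(timepoint_average(frac_mat(f, samples = c("a", "b", "c", "d")),
                                 sheet), "absent")
})

test_that("top clones rank by fraction with lexicographic ties", {
  f <- frac_mat(matrix(c(0.5, 0.3, 0.2), ncol = 1),
                barcodes = c("CCC", "AAA", "TTT"))
  tc <- top_clones(f, n = 10)
  expect_identical(tc$top[[1]], c("CCC", "AAA", "TTT"))
  tie <- frac_mat(matrix(c(0.6, 0.2, 0.2), ncol = 1),
                  barcodes = c("GGG", "TTT", "AAA"))
  expect_identical(top_clones(tie, n = 2)$top[[1]], c("GGG", "AAA"))
  withr::with_seed(8, {
    r <- frac_mat(matrix(runif(50), ncol = 1))
    r <- r / sum(r)
    got <- top_clones(r, n = 10)$top[[1]]
    want <- rownames(r)[order(-r[, 1], rownames(r))][1:10]
    expect_identical(got, want)
  })
  expect_true(all(colSums(top_clones(f, 2)$star) <= 2))
})

test_that("bias detection applies the fold rule with recorded epsilon", {
  avg <- frac_mat(matrix(c(0.10, 0.90, 0.01, 0.99), ncol = 2),
                  barcodes = c("AAA", "CCC"),
                  samples = c("liver:T", "PB:T"))
  calls <- detect_biased_clones(avg, threshold = 5, screen = "all")
  expect_identical(calls$barcode, "AAA")
  expect_identical(calls$location, "liver:T")
  expect_equal(calls$fold, 10)
  not <- frac_mat(matrix(c(0.10, 0.90, 0.05, 0.95), ncol = 2),
                  barcodes = c("AAA", "CCC"),
                  samples = c("liver:T", "PB:T"))
  expect_equal(nrow(detect_biased_clones(not, 5, screen = "all")), 0)
  absent <- frac_mat(matrix(c(0.10, 0.90, 0, 1), ncol = 2),
                     barcodes = c("AAA", "CCC"),
                     samples = c("liver:T", "PB:T"))
  calls2 <- detect_biased_clones(absent, 5, epsilon = 1e-6, screen = "all")
  a <- calls2[calls2$barcode == "AAA" & calls2$location == "liver:T", ]
  expect_equal(a$fold, 1e5)
  expect_equal(a$epsilon, 1e-6)
  expect_error(detect_biased_clones(avg[, 1, drop = FALSE]), "2 locations")
})

test_that("bias calls are scale-invariant and monotone in threshold", {
  withr::with_seed(12, {
    counts <- matrix(rpois(300, 40), 50, 6,
                     dimnames = list(sprintf("B%02d", 1:50),
                                     sprintf("s%d", 1:6)))
    counts[3, 1] <- 2000L
  })
  sheet <- tiny_sheet(tissues = c("PB", "liver", "spleen"))[1:6, ]
  sheet$sample_id <- colnames(counts)
  f1 <- to_fractional_abundance(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 13L
  f2 <- to_fractional_abundance(scaled)
  a1 <- timepoint_average(f1, sheet)
  a2 <- timepoint_average(f2, sheet)
  c1 <- detect_biased_clones(a1, 5, epsilon = 1e-6)
  c2 <- detect_biased_clones(a2, 5, epsilon = 1e-6)
  expect_equal(c1, c2)
  looser <- detect_biased_clones(a1, 2, epsilon = 1e-6)
  stricter <- detect_biased_clones(a1, 8, epsilon = 1e-6)
  key <- function(d) paste(d$barcode, d$location)
  expect_true(all(key(c1) %in% key(looser)))
  expect_true(all(key(stricter) %in% key(c1)))
})

test_that("aggregate top-clone contributions behave definitionally", {
  sheet <- tiny_sheet()
  withr::with_seed(3, {
    f <- matrix(runif(4 * 12), 12, 4,
                dimnames = list(sprintf("B%02d", 1:12), sheet$sample_id))
    f <- sweep(f, 2, colSums(f), "/")
  })
  agg <- aggregate_top_contribution(f, sheet, "PB", "T", n = 5)
  avg <- timepoint_average(f, sheet)
  self <- agg$contributions$contribution[agg$contributions$location == "PB:T"]
  expect_equal(self, sum(avg[agg$top_barcodes, "PB:T"]))
  expect_true(all(agg$contributions$contribution >= 0 &
                    agg$contributions$contribution <= 1))
  # identical composition in both locations (PB cols 1,3; liver cols 2,4)
  f_same <- f
  f_same[, c(2, 4)] <- f[, c(1, 3)]
  agg2 <- aggregate_top_contribution(f_same, sheet, "PB", "T", n = 5)
  expect_equal(agg2$contributions$contribution[1],
               agg2$contributions$contribution[2])
  # disjoint composition -> zero contribution to the other location
  f_dis <- f
  f_dis[1:6, c(1, 3)] <- 0
  f_dis[7:12, c(2, 4)] <- 0
  f_dis <- sweep(f_dis, 2, colSums(f_dis), "/")
  agg3 <- aggregate_top_contribution(f_dis, sheet, "PB", "T", n = 6)
  expect_equal(agg3$contributions$contribution[2], 0)
  # with N = all clones, self-contribution reaches 1
  full <- aggregate_top_contribution(f, sheet, "PB", "T", n = 12)
  expect_equal(full$contributions$contribution[1], 1)
  expect_error(aggregate_top_contribution(f, sheet, "BAL", "T"), "unknown")
})

test_that("shared-clone summary matches set operations", {
  sheet <- tiny_sheet()
  f <- frac_mat(matrix(c(0.5, 0.5, 0, 0,
                         0.6, 0.4, 0, 0,
                         0, 0, 0.3, 0.7,
                         0, 0, 0.2, 0.8), nrow = 4),
                samples = sheet$sample_id)
  same <- shared_clone_summary(f, sheet$sample_id[1], sheet$sample_id[2])
  expect_equal(same$jaccard, 1)
  expect_equal(same$a_only, 0)
  dis <- shared_clone_summary(f, sheet$sample_id[1:2], sheet$sample_id[3:4])
  expect_equal(dis$jaccard, 0)
  expect_equal(dis$shared, 0)
  withr::with_seed(9, {
    r <- frac_mat(matrix(runif(80) * (runif(80) > 0.4), 20, 4),
                  samples = sheet$sample_id)
    r <- sweep(r, 2, pmax(colSums(r), 1e-12), "/")
    got <- shared_clone_summary(r, sheet$sample_id[1:2], sheet$sample_id[3:4])
    in_a <- rowMeans(r[, 1:2]) > 0
    in_b <- rowMeans(r[, 3:4]) > 0
    expect_equal(got$shared, sum(in_a & in_b))
    expect_equal(got$jaccard, sum(in_a & in_b) / sum(in_a | in_b))
    expect_equal(got$shared_mass_a, sum(rowMeans(r[, 1:2])[in_a & in_b]))
  })
  expect_error(shared_clone_summary(f, sheet$sample_id[1:2],
                                    sheet$sample_id[2:3]), "disjoint")
})
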