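test_that("ARI matches the printed worked cases and conventions", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # label permutation invariance
  expect_equal(adjusted_rand_index(c(2, 2, 1, 1), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c("a", "a", "b", "b"), c(5, 5, 9, 9)), 1)
  # both single-cluster partitions: 1 by convention
  expect_equal(adjusted_rand_index(rep(1, 6), rep(2, 6)), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "different lengths")
})

test_that("ARI equals the pair-counting oracle on random instances", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    pred <- sample(1:sample(2:5, 1), n, replace = TRUE)
    truth <- sample(1:sample(2:5, 1), n, replace = TRUE)
    if (length(unique(pred)) == 1 && length(unique(truth)) == 1) next
    expect_equal(adjusted_rand_index(pred, truth), oracle_ari(pred, truth),
                 tolerance = 1e-12)
  }
  # symmetry and boundedness
  set.seed(32)
  p <- sample(1:3, 40, replace = TRUE); t <- sample(1:4, 40, replace = TRUE)
  expect_equal(adjusted_rand_index(p, t), adjusted_rand_index(t, p))
  expect_lte(adjusted_rand_index(p, t), 1)
  # independent cross-check against mclust's implementation
  expect_equal(adjusted_rand_index(p, t), mclust::adjustedRandIndex(p, t))
})

test_that("random labellings score near zero on average", {
  set.seed(33)
  truth <- rep(1:4, each = 25)
  aris <- replicate(200, adjusted_rand_index(sample(1:4, 100, replace = TRUE),
                                             truth))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("silhouette matches the brute-force oracle and its limits", {
  set.seed(34)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(x, lab), oracle_silhouette(x, lab),
                 tolerance = 1e-12)
  }

  # two tight, far-apart clouds approach 1
  far <- rbind(matrix(rnorm(60, sd = 0.01), 30, 2),
               matrix(rnorm(60, sd = 0.01), 30, 2) + 10)
  expect_gte(silhouette_score(far, rep(1:2, each = 30)), 0.99)

  # all points identical: 0 by the a = b convention
  same <- matrix(1, 10, 2)
  expect_equal(silhouette_score(same, rep(1:2, 5)), 0)
  expect_error(silhouette_score(far, rep(1, 60)), "two clusters")
})

test_that("label CSV evaluation joins on barcode", {
  dir <- withr::local_tempdir()
  fx <- small_fixture()
  lab <- refine_labels(fx$labels, fx$spots, r = 10L)
  pred_file <- file.path(dir, "labels.csv")
  write_labels(lab, fx$spots, pred_file)
  truth_file <- file.path(dir, "truth.csv")
  write.csv(data.frame(barcode = rev(fx$spots$barcode),
                       domain = rev(fx$labels)),
            truth_file, row.names = FALSE)
  out <- evaluate_labels(pred_file, truth_file)
  expect_equal(out$ari_raw, 1)
  expect_equal(out$ari_refined, 1)
})
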