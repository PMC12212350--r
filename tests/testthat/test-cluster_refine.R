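separated_clouds <- function(n_per = 40, k = 2, dim = 4, sep = 10, seed = 21) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * dim), n_per, dim), 2,
          c(i * sep, rep(0, dim - 1)), "+")
  }))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}

test_that("hybrid profile concatenates per-block top PCs", {
  set.seed(14)
  Hg <- matrix(rnorm(120 * 50), 120, 50)
  Hi <- matrix(rnorm(120 * 40), 120, 40)
  prof <- build_hybrid_profile(Hg, Hi, p_gene = 30L, p_image = 5L)
  expect_equal(ncol(prof), 35L)
  expect_equal(attr(prof, "block"), rep(c("gene", "image"), c(30, 5)))
  # PC variances are non-increasing within each block
  ve <- attr(prof, "variance_explained")
  expect_true(all(diff(ve$gene) <= 1e-12))
  expect_true(all(diff(ve$image) <= 1e-12))
  # gene block equals a direct PCA oracle up to column signs
  sc <- prcomp(Hg, center = TRUE)$x[, 1:30]
  agree <- abs(colSums(prof[, 1:30] * sc)) /
    (sqrt(colSums(prof[, 1:30]^2)) * sqrt(colSums(sc^2)))
  expect_true(all(agree > 1 - 1e-8))

  # variance mode caps at the attainable rank
  lowrank <- matrix(rnorm(120 * 3), 120, 3) %*% matrix(rnorm(3 * 20), 3, 20)
  prof2 <- build_hybrid_profile(Hg, lowrank, p_gene = 5L, var_image = 1)
  expect_equal(sum(attr(prof2, "block") == "image"), 3L)
  expect_error(build_hybrid_profile(lowrank, NULL, p_gene = 10L),
               "rank")

  # duplicating every row leaves the PC subspace unchanged (up to sign)
  dup <- build_hybrid_profile(rbind(Hg, Hg), NULL, p_gene = 10L)
  half <- dup[1:120, ]
  ref <- build_hybrid_profile(Hg, NULL, p_gene = 10L)
  cors <- abs(diag(cor(half, ref)))
  expect_true(all(cors > 1 - 1e-6))

  # image features may arrive as an N x C x F array
  arr <- array(Hi, dim = c(120, 2, 20))
  prof3 <- build_hybrid_profile(Hg, arr, p_gene = 4L, p_image = 4L)
  expect_equal(ncol(prof3), 8L)
})

test_that("mixture clustering recovers well-separated clouds exactly", {
  cl <- separated_clouds(sep = 10)
  lab <- cluster_domains(cl$x, 2L)
  expect_equal(adjusted_rand_index(lab$raw, cl$truth), 1)
  expect_setequal(unique(lab$raw), 1:2)
  # deterministic backend: identical labels on repeat
  expect_identical(cluster_domains(cl$x, 2L)$raw, lab$raw)
  expect_error(cluster_domains(cl$x, nrow(cl$x)), "smaller")
  expect_error(cluster_domains(cl$x, 1L), ">= 2")
})

test_that("silhouette-based selection finds the planted number of clouds", {
  two <- separated_clouds(n_per = 30, k = 2, sep = 12, seed = 22)
  expect_equal(as.integer(choose_k_by_silhouette(two$x, 2:5)), 2L)
  three <- separated_clouds(n_per = 25, k = 3, sep = 12, seed = 23)
  expect_equal(as.integer(choose_k_by_silhouette(three$x, 2:5)), 3L)
})

test_that("refinement takes the neighbourhood majority with stable ties", {
  fx <- small_fixture()
  # spatially coherent labels: refinement is the identity
  coherent <- fx$labels
  ref <- refine_labels(coherent, fx$spots, r = 10L)
  expect_equal(ref$refined, coherent)

  # a spot relabelled against a unanimous neighbourhood flips
  noisy <- coherent
  i <- which(fx$spots$array_row == 2 & fx$spots$array_col == 5)
  noisy[i] <- 2L   # deep inside domain 1
  ref2 <- refine_labels(noisy, fx$spots, r = 10L)
  expect_equal(ref2$refined[i], 1L)

  # never invents labels; single pass uses pre-refinement labels only
  set.seed(24)
  scrambled <- sample(coherent)
  ref3 <- refine_labels(scrambled, fx$spots, r = 10L)
  expect_true(all(ref3$refined %in% unique(scrambled)))

  # even-split tie keeps the spot's own label when it participates in the
  # tie, else the smallest tied label wins
  strip <- tiny_spots(rep(0, 4), c(0, 100, 200, 300))
  paired <- c(1L, 1L, 2L, 2L)
  ref4 <- refine_labels(paired, strip, r = 2L)
  # spots 2 and 3 each see one label-1 and one label-2 neighbour: tie -> keep
  expect_equal(ref4$refined, paired)
  mixed <- c(1L, 3L, 1L, 3L)
  ref5 <- refine_labels(mixed, strip, r = 2L)
  # spot 2 (label 3) sees {1, 1} -> flips; spot 3 (label 1) sees {3, 3} -> flips
  expect_equal(ref5$refined[2:3], c(1L, 3L))

  expect_error(refine_labels(paired, strip, r = 4L), "smaller")
})

test_that("refining noisy ground truth raises neighbourhood purity", {
  fx <- small_fixture()
  set.seed(25)
  noisy <- fx$labels
  flip <- sample(length(noisy), round(0.1 * length(noisy)))
  noisy[flip] <- sample(1:2, length(flip), replace = TRUE)
  before <- neighbourhood_purity(noisy, fx$spots, r = 10)
  ref <- refine_labels(noisy, fx$spots, r = 10L)
  after <- neighbourhood_purity(ref$refined, fx$spots, r = 10)
  expect_gt(after, before)
  expect_gt(adjusted_rand_index(ref$refined, fx$labels),
            adjusted_rand_index(noisy, fx$labels))
})
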