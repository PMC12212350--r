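test_that("spot grids use the ceiling of the spot diameter and crop centred", {
  px <- matrix(seq(0, 1, length.out = 200 * 200), 200, 200)
  spots <- tiny_spots(c(100, 60), c(100, 130), diameter = 89.4)
  grids <- extract_spot_grids(list(channel_image(px, "CH1")), spots)
  expect_equal(grids$d, 90L)
  expect_equal(dim(grids$grids), c(2L, 1L, 48L, 48L))

  # constant channel gives constant grids at that value
  const <- extract_spot_grids(list(channel_image(matrix(7, 200, 200), "c")),
                              spots)
  expect_equal(max(abs(const$grids - 7)), 0)

  # centroid at the border errors unless padding is enabled
  edge <- tiny_spots(c(0, 100), c(0, 100), diameter = 55)
  expect_error(extract_spot_grids(list(channel_image(px, "CH1")), edge),
               "BC0001")
  padded <- extract_spot_grids(list(channel_image(px, "CH1")), edge,
                               pad_edges = TRUE)
  expect_equal(dim(padded$grids)[1], 2L)
})

test_that("area-average resize matches block means and preserves constants", {
  # integer ratio: each output pixel is the mean of its 2x2 source block
  set.seed(11)
  src <- matrix(runif(96 * 96), 96, 96)
  out <- resize_grid(src, 48L)
  oracle <- matrix(0, 48, 48)
  for (i in 1:48) for (j in 1:48) {
    oracle[i, j] <- mean(src[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(out, oracle)

  # identity at equal size; constant preserved at awkward ratios
  same <- matrix(runif(48 * 48), 48, 48)
  expect_equal(resize_grid(same, 48L), same)
  expect_equal(resize_grid(matrix(3.3, 55, 55), 48L),
               matrix(3.3, 48, 48))
  # mass preservation: global mean unchanged by exact pixel mixing
  odd <- matrix(runif(55 * 55), 55, 55)
  expect_equal(mean(resize_grid(odd, 48L)), mean(odd), tolerance = 1e-12)
})

test_that("grid normalization maps channel ranges onto the expression range", {
  fx <- small_fixture()
  grids <- extract_spot_grids(fx$channels, fx$spots)
  ref <- matrix(c(-4, 10), 2, 2)   # range [-4, 10]
  out <- normalize_grids(grids, ref)
  expect_equal(range(out$grids), c(-4, 10))

  # endpoints map linearly: a two-valued channel hits exactly the endpoints
  g2 <- grids
  g2$grids[] <- 0; g2$grids[1, 1, 1, 1] <- 255
  out2 <- normalize_grids(g2, ref)
  expect_equal(out2$grids[1, 1, 1, 1], 10)
  expect_equal(out2$grids[2, 1, 1, 1], -4)

  # constant channel maps to the midpoint
  g3 <- grids
  g3$grids[] <- 5
  expect_equal(unique(as.numeric(normalize_grids(g3, ref)$grids)), 3)
})

test_that("CNN autoencoder trains the reconstruction loss down, deterministically", {
  fx <- small_fixture()
  grids <- normalize_grids(extract_spot_grids(fx$channels, fx$spots),
                           matrix(c(0, 1), 2))
  cfg <- cnn_config(n_iter = 120L, batch_size = 32L, seed = 5L)
  fit <- train_cnn_autoencoder(grids, cfg)
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])
  expect_equal(dim(fit$features), c(100L, 1L, 48L * 48L))
  expect_true(all(is.finite(fit$features)))

  fit2 <- train_cnn_autoencoder(grids, cfg)
  expect_identical(fit$features, fit2$features)

  # identical grids give identical features; equal grids give ~zero spread
  g_eq <- grids
  for (i in seq_len(dim(g_eq$grids)[1])) g_eq$grids[i, 1, , ] <- grids$grids[1, 1, , ]
  fit_eq <- train_cnn_autoencoder(g_eq, cnn_config(n_iter = 30L, seed = 2L))
  flat <- matrix(fit_eq$features, nrow = 100)
  expect_lt(max(dist(flat[c(1, 25, 50, 75), ])), 1e-8)
})

test_that("the trained forward map is equivariant to spot reordering", {
  fx <- small_fixture()
  grids <- normalize_grids(extract_spot_grids(fx$channels, fx$spots),
                           matrix(c(0, 1), 2))
  fit <- train_cnn_autoencoder(grids, cnn_config(n_iter = 25L, seed = 3L))
  perm <- sample(seq_len(100))
  g_perm <- grids
  g_perm$grids <- grids$grids[perm, , , , drop = FALSE]
  expect_equal(cnn_forward(fit, g_perm), cnn_forward(fit, grids)[perm, ],
               tolerance = 1e-6)
})
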