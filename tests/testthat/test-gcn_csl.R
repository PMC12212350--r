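two_spot_graph <- function() {
  build_knn_graph(tiny_spots(c(0, 0), c(0, 1)), k = 1)
}

test_that("encoder and decoder follow the printed recursions", {
  g <- two_spot_graph()                       # L = [[1,1],[1,1]]
  state <- list(We = list(matrix(1)), be = list(0),
                Wd = list(matrix(1)), bd = list(0))
  X <- matrix(c(1, 0), 2, 1)
  expect_equal(gcn_encode(X, g, state), matrix(c(1, 1), 2, 1))
  expect_equal(gcn_decode(matrix(c(1, 0), 2, 1), g, state),
               matrix(c(1, 1), 2, 1))

  # zero input, zero bias -> zero output through any depth
  state2 <- list(We = list(matrix(rnorm(4), 1, 4), matrix(rnorm(8), 4, 2)),
                 be = list(numeric(4), numeric(2)),
                 Wd = list(matrix(rnorm(8), 2, 4), matrix(rnorm(4), 4, 1)),
                 bd = list(numeric(4), numeric(1)))
  Z0 <- gcn_encode(matrix(0, 2, 1), g, state2)
  expect_equal(Z0, matrix(0, 2, 2))
  expect_equal(gcn_decode(Z0, g, state2), matrix(0, 2, 1))

  # dense-oracle check on a random case, including the mirrored shapes
  set.seed(8)
  spots <- tiny_spots(runif(12, 0, 50), runif(12, 0, 50))
  gg <- build_knn_graph(spots, k = 3)
  Ld <- as.matrix(gg$L)
  X12 <- matrix(rnorm(12 * 5), 12, 5)
  st <- spotfuse:::gcn_init_state(5, c(4L, 3L), seed = 1)
  relu <- function(m) pmax(m, 0)
  Z_oracle <- relu(Ld %*% relu(Ld %*% X12 %*% st$We[[1]] +
                                 matrix(st$be[[1]], 12, 4, byrow = TRUE)) %*%
                     st$We[[2]] + matrix(st$be[[2]], 12, 3, byrow = TRUE))
  expect_equal(gcn_encode(X12, gg, st), Z_oracle)
  H <- gcn_decode(Z_oracle, gg, st)
  expect_equal(dim(H), c(12L, 5L))

  # permutation equivariance of the forward pass
  perm <- sample(12)
  gp <- gg; gp$L <- gg$L[perm, perm]
  expect_equal(gcn_encode(X12[perm, ], gp, st), Z_oracle[perm, ])
})

test_that("corruption permutes rows, preserves the multiset, reproducibly", {
  set.seed(10)
  X <- matrix(rnorm(40), 10, 4)
  Xc <- corrupt_features(X, seed = 3)
  expect_false(identical(Xc[seq_len(10), ], X))
  expect_equal(X[attr(Xc, "perm"), ], unclass(Xc), ignore_attr = TRUE)
  srt <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(srt(unclass(Xc)), srt(X))
  expect_identical(corrupt_features(X, seed = 3), Xc)
  # N = 2 is forced to swap
  X2 <- matrix(1:4, 2, 2)
  expect_equal(unclass(corrupt_features(X2, seed = 1)), X2[c(2, 1), ],
               ignore_attr = TRUE)
})

test_that("read-out and discriminator match their closed forms", {
  g <- two_spot_graph()
  # zero embeddings: S = 0.5 everywhere
  expect_equal(readout(matrix(0, 2, 3), g), matrix(0.5, 2, 3))
  # large positive own embedding, zero neighbours: saturates towards 1
  Zbig <- rbind(rep(50, 3), rep(0, 3))
  expect_gt(min(readout(Zbig, g)[1, ]), 0.999999)

  # brute-force neighbour sum on a honeycomb interior spot
  fx <- small_fixture()
  gh <- build_knn_graph(fx$spots, k = 6)
  set.seed(12)
  Z <- matrix(rnorm(nrow(fx$spots) * 4), ncol = 4)
  i <- which(fx$spots$array_row == 4 & fx$spots$array_col == 4)
  nb <- which(as.matrix(gh$A)[i, ] == 1)
  expect_equal(readout(Z, gh)[i, ],
               1 / (1 + exp(-(colMeans(Z[nb, ]) + Z[i, ]))))

  # discriminator: identity W on a unit basis vector gives sigmoid(1)
  e1 <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(discriminate(e1, e1, diag(3)), 1 / (1 + exp(-1)))
  expect_equal(discriminate(matrix(0, 1, 3), e1, diag(3)), 0.5)
  # sign flip of Z maps p to 1 - p
  W <- matrix(rnorm(9), 3, 3)
  S <- matrix(runif(3), 1, 3)
  Zr <- matrix(rnorm(3), 1, 3)
  expect_equal(discriminate(-Zr, S, W), 1 - discriminate(Zr, S, W))
})

test_that("contrastive losses match the scalar oracle and its limits", {
  # all scores 0.5 (zero embeddings) -> log 2 per loss
  Z <- matrix(0, 4, 3)
  out <- csl_loss(Z, Z, matrix(0.5, 4, 3), matrix(0.5, 4, 3), diag(3))
  expect_equal(out$csl, log(2))
  expect_equal(out$csl_corrupt, log(2))

  # random small instances agree with the term-by-term expansion to 1e-6
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(2:10, 1); f <- sample(2:4, 1)
    Z <- matrix(rnorm(n * f), n, f)
    Zc <- Z[sample(n), , drop = FALSE]
    S <- matrix(runif(n * f), n, f)
    Sc <- matrix(runif(n * f), n, f)
    W <- matrix(rnorm(f * f), f, f)
    got <- csl_loss(Z, Zc, S, Sc, W)
    want <- oracle_csl(Z, Zc, S, Sc, W)
    expect_equal(got$csl, want$csl, tolerance = 1e-6)
    expect_equal(got$csl_corrupt, want$csl_corrupt, tolerance = 1e-6)
  }

  # perfect discrimination drives both losses towards zero: real and
  # corrupted embeddings each align with their own summaries and oppose the
  # other's
  big <- 60
  Zp <- matrix(big, 2, 1); Zn <- matrix(-big, 2, 1)
  S_real <- matrix(1, 2, 1); S_corr <- matrix(-1, 2, 1)
  out2 <- csl_loss(Zp, Zn, S_real, S_corr, matrix(1))
  expect_lt(out2$csl, 1e-6)
  expect_lt(out2$csl_corrupt, 1e-6)
})

test_that("modality training reduces the loss and separates pair scores", {
  fx <- small_fixture()
  g <- build_knn_graph(fx$spots, k = 6)
  scaled <- normalize_expression(
    select_hvgs(normalize_expression(filter_genes(fx$expr), scale = FALSE), 80L))
  cfg <- gcn_config(encoder_dims = c(32L, 16L), n_iter = 150L, seed = 4L)
  emb <- train_modality(scaled$values, g, cfg)
  ls <- emb$losses
  expect_lt(ls$total[nrow(ls)], ls$total[1])
  expect_equal(dim(emb$Z), c(100L, 16L))
  expect_equal(dim(emb$H), dim(scaled$values))

  # after training, positive pairs outscore negative (corrupted) pairs
  S <- readout(emb$Z, g)
  Zc <- gcn_encode(corrupt_features(scaled$values, seed = 99), g, emb$state)
  p_pos <- discriminate(emb$Z, S, emb$state$Wdisc)
  p_neg <- discriminate(Zc, S, emb$state$Wdisc)
  expect_gt(mean(p_pos), mean(p_neg))

  # determinism under the config seed
  emb2 <- train_modality(scaled$values, g, cfg)
  expect_identical(emb$Z, emb2$Z)
})

test_that("the compiled training loop matches the reference R implementation", {
  set.seed(17)
  spots <- tiny_spots(runif(40, 0, 200), runif(40, 0, 200))
  g <- build_knn_graph(spots, k = 4)
  X <- matrix(rnorm(40 * 12), 40, 12)
  cfg <- gcn_config(encoder_dims = c(6L, 3L), n_iter = 40L, seed = 11L)
  fast <- train_modality(X, g, cfg)
  ref <- spotfuse:::train_modality_r(X, g, cfg)
  expect_equal(fast$Z, ref$Z, tolerance = 1e-10)
  expect_equal(fast$H, ref$H, tolerance = 1e-10)
  expect_equal(fast$losses$total, ref$losses$total, tolerance = 1e-10)
})

test_that("pure reconstruction (beta = 0) decreases monotonically and beats
           the contrastive run on reconstruction error", {
  fx <- small_fixture()
  g <- build_knn_graph(fx$spots, k = 6)
  scaled <- normalize_expression(
    select_hvgs(normalize_expression(filter_genes(fx$expr), scale = FALSE), 80L))
  cfg0 <- gcn_config(encoder_dims = c(32L, 16L), n_iter = 400L, beta = 0,
                     seed = 6L)
  emb0 <- train_modality(scaled$values, g, cfg0)
  checkpoints <- emb0$losses$recon[seq(100, 400, by = 100)]
  violations <- sum(diff(checkpoints) > 0)
  expect_lte(violations, 1)

  # ablation: with the contrastive terms weighted enough to matter, the pure
  # reconstruction run ends at a lower reconstruction error
  cfg1 <- gcn_config(encoder_dims = c(32L, 16L), n_iter = 400L, beta = 1e5,
                     seed = 6L)
  emb1 <- train_modality(scaled$values, g, cfg1)
  expect_lt(emb0$losses$recon[400], emb1$losses$recon[400])
})
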