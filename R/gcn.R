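#' GCN autoencoder / contrastive-learning configuration
#'
#' @param encoder_dims widths of the graph-convolution encoder layers; the
#'   decoder mirrors them in reverse. The last entry is the latent dimension.
#' @param lr Adam learning rate.
#' @param n_iter number of full-graph optimizer steps.
#' @param alpha weight of the summed squared reconstruction loss.
#' @param beta weight of the two contrastive terms.
#' @param seed integer seed (weight initialization and the per-iteration
#'   corruption permutations).
#' @return list of class `gcn_config`.
#' @export
gcn_config <- function(encoder_dims = c(64L, 32L), lr = 1e-3, n_iter = 600L,
                       alpha = 1, beta = 1, seed = 1L) {
  stopifnot(length(encoder_dims) >= 1L, alpha >= 0, beta >= 0)
  structure(list(encoder_dims = as.integer(encoder_dims), lr = lr,
                 n_iter = as.integer(n_iter), alpha = alpha, beta = beta,
                 seed = as.integer(seed)),
            class = "gcn_config")
}

# Trainable state: encoder weight/bias per layer, mirrored decoder, bilinear
# discriminator matrix (latent x latent), seeded uniform Glorot init.
# Decoder biases start at a small positive value: the decoder consumes
# non-negative (ReLU'd, graph-averaged) activations, and with zero biases an
# unlucky Glorot draw can leave whole decoder layers below the ReLU threshold
# with exactly zero gradient — permanently dead. A +0.1 offset keeps every
# decoder unit initially active without biasing the converged solution.
gcn_init_state <- function(n_features, encoder_dims, seed) {
  set.seed(seed)
  dims <- c(n_features, encoder_dims)
  nl <- length(encoder_dims)
  We <- be <- vector("list", nl)
  for (l in seq_len(nl)) {
    We[[l]] <- glorot(dims[l], dims[l + 1])
    be[[l]] <- numeric(dims[l + 1])
  }
  rdims <- rev(dims)
  Wd <- bd <- vector("list", nl)
  for (l in seq_len(nl)) {
    Wd[[l]] <- glorot(rdims[l], rdims[l + 1])
    bd[[l]] <- rep(0.1, rdims[l + 1])
  }
  d <- encoder_dims[nl]
  list(We = We, be = be, Wd = Wd, bd = bd, Wdisc = glorot(d, d))
}

#' Graph convolutional encoder
#'
#' Applies the encoder recursion `Z^{t+1} = ReLU(L Z^t W_e^t + b_e^t)` with
#' `Z^0 = X`, returning the final latent matrix.
#'
#' @param X numeric matrix `N x F` of spot features.
#' @param L the normalized Laplacian (from [build_knn_graph()]), or a
#'   `spatial_graph`.
#' @param state a GCN state list with elements `We`, `be` (see
#'   [train_modality()]).
#' @return latent matrix `Z` (`N x` last encoder width).
#' @export
gcn_encode <- function(X, L, state) {
  if (inherits(L, "spatial_graph")) L <- L$L
  if (nrow(X) != nrow(L)) stop("X and L have mismatched numbers of spots")
  Z <- X
  for (l in seq_along(state$We)) {
    Z <- relu(as.matrix(L %*% Z) %*% state$We[[l]] +
                rep_row(state$be[[l]], nrow(X)))
  }
  Z
}

#' Graph convolutional decoder
#'
#' Applies the mirrored decoder recursion `H^{t-1} = ReLU(L H^t W_d^t +
#' b_d^t)` starting from the latent `Z`, returning the reconstructed feature
#' matrix with the input feature width.
#'
#' @param Z latent matrix from [gcn_encode()].
#' @param L the normalized Laplacian or a `spatial_graph`.
#' @param state a GCN state list with elements `Wd`, `bd`.
#' @return reconstructed feature matrix `H` (`N x F`).
#' @export
gcn_decode <- function(Z, L, state) {
  if (inherits(L, "spatial_graph")) L <- L$L
  H <- Z
  for (l in seq_along(state$Wd)) {
    H <- relu(as.matrix(L %*% H) %*% state$Wd[[l]] +
                rep_row(state$bd[[l]], nrow(H)))
  }
  H
}

#' Corrupt spot features by row shuffling
#'
#' Generates the negative-sample features for contrastive learning: the rows
#' of `X` are permuted by a seeded random permutation while the spatial graph
#' is left untouched, so each spot keeps its neighbourhood but receives
#' another spot's biological profile. The multiset of feature rows is
#' preserved. For `N = 2` the swap is forced so the corruption is never the
#' identity.
#'
#' @param X numeric matrix `N x F`.
#' @param seed integer seed.
#' @return the row-permuted matrix, with the permutation as attribute `perm`.
#' @export
corrupt_features <- function(X, seed = 1L) {
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 spots to corrupt")
  set.seed(seed)
  perm <- if (n == 2L) c(2L, 1L) else sample.int(n)
  out <- X[perm, , drop = FALSE]
  attr(out, "perm") <- perm
  out
}

#' Neighbourhood read-out summary
#'
#' Summarizes each spot's local context as `S_i = sigmoid(mean_{j in N(i)}
#' Z_j + Z_i)`, the logistic sigmoid of the mean neighbour embedding plus the
#' spot's own embedding; summaries live in (0, 1). Spots whose degree differs
#' from `k` (boundary spots after union symmetrization) average over their
#' actual neighbour set.
#'
#' @param Z latent matrix `N x d`.
#' @param g a `spatial_graph`.
#' @return summary matrix `S` (`N x d`).
#' @export
readout <- function(Z, g) {
  sigmoid(as.matrix(readout_operator(g) %*% Z))
}

#' Bilinear discriminator score
#'
#' Scores embedding/summary pairs with `D(Z_i, S_i) = sigmoid(Z_i^T W S_i)`.
#'
#' @param Z,S row-aligned matrices (`N x d`).
#' @param W_disc trainable `d x d` scoring matrix.
#' @return vector of probabilities in (0, 1).
#' @export
discriminate <- function(Z, S, W_disc) {
  sigmoid(rowSums((Z %*% W_disc) * S))
}

#' Contrastive self-supervised losses
#'
#' Binary-cross-entropy contrast between positive pairs — each embedding with
#' its own graph summary, `(Z_i, S_i)` and `(Z'_i, S'_i)` — and negative
#' cross pairs `(Z'_j, S_j)` and `(Z_j, S'_j)`, where primes denote the
#' corrupted (feature-shuffled) pass. Each loss averages its `2N` terms;
#' probabilities are clamped to `[eps, 1-eps]` before the log.
#'
#' @param Z,Z_corrupt latent matrices from the real and corrupted pass.
#' @param S,S_corrupt the matching read-out summaries.
#' @param W_disc discriminator matrix.
#' @param eps clamping constant.
#' @return list with `csl` and `csl_corrupt`.
#' @export
csl_loss <- function(Z, Z_corrupt, S, S_corrupt, W_disc, eps = 1e-7) {
  n <- nrow(Z)
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  p_pos <- clamp(discriminate(Z, S, W_disc))
  p_neg <- clamp(discriminate(Z_corrupt, S, W_disc))
  p_pos_c <- clamp(discriminate(Z_corrupt, S_corrupt, W_disc))
  p_neg_c <- clamp(discriminate(Z, S_corrupt, W_disc))
  list(
    csl = -(sum(log(p_pos)) + sum(log(1 - p_neg))) / (2 * n),
    csl_corrupt = -(sum(log(p_pos_c)) + sum(log(1 - p_neg_c))) / (2 * n)
  )
}

#' Train one modality's graph autoencoder with contrastive refinement
#'
#' Full-batch Adam training of the graph convolutional autoencoder on one
#' modality's spot features, minimizing
#' `alpha * ||X - H||_F^2 + beta * (L_CSL + L_CSL_corrupt)`. Each iteration
#' draws a fresh corruption permutation from the seeded stream, runs the
#' shared-weight encoder on the real and corrupted features, scores
#' positive/negative pairs with the bilinear discriminator, and backpropagates
#' through decoder, read-out and encoder. Deterministic given the config
#' seed.
#'
#' @param X numeric matrix `N x F` of preprocessed features (scaled HVG
#'   expression, or flattened per-channel image features).
#' @param g a `spatial_graph` over the same spots.
#' @param cfg a [gcn_config].
#' @param modality label stored on the result (`"expression"` or `"image"`).
#' @return a `modality_embedding`: list with latent `Z`, reconstruction `H`,
#'   `losses` (data.frame iter/total/recon/csl/csl_corrupt), `state`,
#'   `modality`.
#' @export
train_modality <- function(X, g, cfg = gcn_config(),
                           modality = c("expression", "image")) {
  modality <- match.arg(modality)
  X <- as.matrix(X)
  n <- nrow(X); nf <- ncol(X)
  if (n != nrow(g$A)) stop("feature matrix and graph have different spot counts")
  L <- g$L
  Q <- readout_operator(g)
  state <- gcn_init_state(nf, cfg$encoder_dims, cfg$seed)

  # per-iteration corruption permutations, drawn once from the seeded stream
  set.seed(cfg$seed + 1L)
  perms <- matrix(0L, cfg$n_iter, n)
  for (t in seq_len(cfg$n_iter)) perms[t, ] <- sample.int(n)

  fit <- gcn_train_cpp(X, methods::as(L, "dgCMatrix"),
                       methods::as(Q, "dgCMatrix"), perms, state,
                       cfg$alpha, cfg$beta, cfg$lr, cfg$n_iter, 1e-7)
  state <- list(We = fit$We, be = lapply(fit$be, as.numeric),
                Wd = fit$Wd, bd = lapply(fit$bd, as.numeric),
                Wdisc = fit$Wdisc)
  losses <- data.frame(iter = seq_len(cfg$n_iter), total = fit$losses[, 1],
                       recon = fit$losses[, 2], csl = fit$losses[, 3],
                       csl_corrupt = fit$losses[, 4])

  Z <- gcn_encode(X, L, state)
  H <- gcn_decode(Z, L, state)
  structure(list(Z = Z, H = H, modality = modality, losses = losses,
                 state = state, cfg = cfg),
            class = "modality_embedding")
}

# Reference R implementation of the training loop (kept for cross-checking
# the compiled path on small instances; same math, same RNG contract).
train_modality_r <- function(X, g, cfg = gcn_config(),
                             modality = c("expression", "image")) {
  modality <- match.arg(modality)
  X <- as.matrix(X)
  n <- nrow(X); nf <- ncol(X)
  if (n != nrow(g$A)) stop("feature matrix and graph have different spot counts")
  L <- g$L
  Q <- readout_operator(g)
  Qt <- Matrix::t(Q)
  state <- gcn_init_state(nf, cfg$encoder_dims, cfg$seed)
  nl <- length(cfg$encoder_dims)
  np <- 4L * nl + 1L

  adam <- new.env(parent = emptyenv())
  adam$m <- adam$v <- vector("list", np)
  adam_step <- function(idx, w, grad, t) {
    if (is.null(adam$m[[idx]])) {
      adam$m[[idx]] <- 0 * w; adam$v[[idx]] <- 0 * w
    }
    adam$m[[idx]] <- 0.9 * adam$m[[idx]] + 0.1 * grad
    adam$v[[idx]] <- 0.999 * adam$v[[idx]] + 0.001 * grad^2
    mhat <- adam$m[[idx]] / (1 - 0.9^t)
    vhat <- adam$v[[idx]] / (1 - 0.999^t)
    w - cfg$lr * mhat / (sqrt(vhat) + 1e-8)
  }

  LX <- as.matrix(L %*% X)
  eps <- 1e-7
  losses <- data.frame(iter = seq_len(cfg$n_iter), total = NA_real_,
                       recon = NA_real_, csl = NA_real_,
                       csl_corrupt = NA_real_)
  set.seed(cfg$seed + 1L)

  for (t in seq_len(cfg$n_iter)) {
    perm <- sample.int(n)
    Xc <- X[perm, , drop = FALSE]

    # encoder forward, real and corrupted (shared weights)
    Ae <- Pe <- Ze <- vector("list", nl)
    Aec <- Pec <- Zec <- vector("list", nl)
    Zin <- X; Zinc <- Xc
    for (l in seq_len(nl)) {
      Ae[[l]] <- if (l == 1L) LX else as.matrix(L %*% Zin)
      Aec[[l]] <- as.matrix(L %*% Zinc)
      Pe[[l]] <- Ae[[l]] %*% state$We[[l]] + rep_row(state$be[[l]], n)
      Pec[[l]] <- Aec[[l]] %*% state$We[[l]] + rep_row(state$be[[l]], n)
      Zin <- Ze[[l]] <- relu(Pe[[l]])
      Zinc <- Zec[[l]] <- relu(Pec[[l]])
    }
    Z <- Ze[[nl]]; Zc <- Zec[[nl]]

    # decoder forward (real pass only; reconstruction is of the real input)
    Ad <- Pd <- Hd <- vector("list", nl)
    Hin <- Z
    for (l in seq_len(nl)) {
      Ad[[l]] <- as.matrix(L %*% Hin)
      Pd[[l]] <- Ad[[l]] %*% state$Wd[[l]] + rep_row(state$bd[[l]], n)
      Hin <- Hd[[l]] <- relu(Pd[[l]])
    }
    H <- Hd[[nl]]

    # read-out summaries and discriminator scores
    QZ <- as.matrix(Q %*% Z); S <- sigmoid(QZ)
    QZc <- as.matrix(Q %*% Zc); Sc <- sigmoid(QZc)
    ZW <- Z %*% state$Wdisc
    ZcW <- Zc %*% state$Wdisc
    clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
    p_pos <- clamp(sigmoid(rowSums(ZW * S)))
    p_neg <- clamp(sigmoid(rowSums(ZcW * S)))
    p_pos_c <- clamp(sigmoid(rowSums(ZcW * Sc)))
    p_neg_c <- clamp(sigmoid(rowSums(ZW * Sc)))

    recon <- sum((X - H)^2)
    l_csl <- -(sum(log(p_pos)) + sum(log(1 - p_neg))) / (2 * n)
    l_cslc <- -(sum(log(p_pos_c)) + sum(log(1 - p_neg_c))) / (2 * n)
    total <- cfg$alpha * recon + cfg$beta * (l_csl + l_cslc)
    losses[t, 2:5] <- c(total, recon, l_csl, l_cslc)
    if (!is.finite(total)) stop("GCN training loss diverged (non-finite) at iteration ", t)

    # ---- backward ----
    # decoder
    dH <- 2 * cfg$alpha * (H - X)
    dWd <- dbd <- vector("list", nl)
    for (l in rev(seq_len(nl))) {
      dP <- dH * (Pd[[l]] > 0)
      dWd[[l]] <- crossprod(Ad[[l]], dP)
      dbd[[l]] <- colSums(dP)
      dH <- as.matrix(L %*% (dP %*% t(state$Wd[[l]])))
    }
    dZ_dec <- dH

    # contrastive terms: d loss / d score logits (factor beta folded in)
    du_pos <- -cfg$beta * (1 - p_pos) / (2 * n)
    du_neg <- cfg$beta * p_neg / (2 * n)
    du_pos_c <- -cfg$beta * (1 - p_pos_c) / (2 * n)
    du_neg_c <- cfg$beta * p_neg_c / (2 * n)

    Wt <- t(state$Wdisc)
    dZ_csl <- (du_pos * S) %*% Wt + (du_neg_c * Sc) %*% Wt
    dZc_csl <- (du_neg * S) %*% Wt + (du_pos_c * Sc) %*% Wt
    dS <- (du_pos * Z) %*% state$Wdisc + (du_neg * Zc) %*% state$Wdisc
    dSc <- (du_pos_c * Zc) %*% state$Wdisc + (du_neg_c * Z) %*% state$Wdisc
    dWdisc <- crossprod(Z, du_pos * S) + crossprod(Zc, du_neg * S) +
      crossprod(Zc, du_pos_c * Sc) + crossprod(Z, du_neg_c * Sc)

    # through the read-out sigmoid
    dZ_csl <- dZ_csl + as.matrix(Qt %*% (dS * S * (1 - S)))
    dZc_csl <- dZc_csl + as.matrix(Qt %*% (dSc * Sc * (1 - Sc)))

    # encoder (shared weights accumulate real + corrupted gradients)
    dWe <- dbe <- vector("list", nl)
    dZ <- dZ_dec + dZ_csl
    dZc <- dZc_csl
    for (l in rev(seq_len(nl))) {
      dP <- dZ * (Pe[[l]] > 0)
      dPc <- dZc * (Pec[[l]] > 0)
      dWe[[l]] <- crossprod(Ae[[l]], dP) + crossprod(Aec[[l]], dPc)
      dbe[[l]] <- colSums(dP) + colSums(dPc)
      if (l > 1L) {
        dZ <- as.matrix(L %*% (dP %*% t(state$We[[l]])))
        dZc <- as.matrix(L %*% (dPc %*% t(state$We[[l]])))
      }
    }

    # Adam updates
    for (l in seq_len(nl)) {
      state$We[[l]] <- adam_step(l, state$We[[l]], dWe[[l]], t)
      state$be[[l]] <- adam_step(nl + l, state$be[[l]], dbe[[l]], t)
      state$Wd[[l]] <- adam_step(2L * nl + l, state$Wd[[l]], dWd[[l]], t)
      state$bd[[l]] <- adam_step(3L * nl + l, state$bd[[l]], dbd[[l]], t)
    }
    state$Wdisc <- adam_step(np, state$Wdisc, dWdisc, t)
  }

  Z <- gcn_encode(X, L, state)
  H <- gcn_decode(Z, L, state)
  structure(list(Z = Z, H = H, modality = modality, losses = losses,
                 state = state, cfg = cfg),
            class = "modality_embedding")
}

#' @export
print.modality_embedding <- function(x, ...) {
  cat(sprintf("<modality_embedding> %s: %d spots, latent %d, final loss %.4g\n",
              x$modality, nrow(x$Z), ncol(x$Z),
              x$losses$total[nrow(x$losses)]))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)
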