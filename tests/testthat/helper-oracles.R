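# Independent brute-force oracles; deliberately naive, kept free of any
# package internals so they can arbitrate.

# ARI by explicit enumeration of all N*(N-1)/2 observation pairs.
oracle_ari <- function(pred, truth) {
  n <- length(pred)
  a <- b <- cd <- 0  # agreements: together/together, apart/apart, disagreements
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_p <- pred[i] == pred[j]
      same_t <- truth[i] == truth[j]
      if (same_p && same_t) a <- a + 1
      else if (!same_p && !same_t) b <- b + 1
      else cd <- cd + 1
    }
  }
  total <- a + b + cd
  # expected index from margins, via pair counts
  np <- sum(choose(table(pred), 2))
  nt <- sum(choose(table(truth), 2))
  expected <- np * nt / total
  max_index <- (np + nt) / 2
  if (max_index == expected) return(1)
  (a - expected) / (max_index - expected)
}

# Mean silhouette width by direct O(N^2) computation.
oracle_silhouette <- function(x, lab) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(d[i, lab == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Directed kNN by full sort per spot, union-symmetrized; ties by index.
oracle_knn_adjacency <- function(xy, k) {
  n <- nrow(xy)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xy) - xy[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    A[i, nb] <- 1
  }
  pmax(A, t(A))
}

# Windowed maximum with explicit window scan (box window spanning
# floor(box/2) before to box-1-floor(box/2) after, truncated at borders).
oracle_windowed_max <- function(px, box) {
  lo <- -(box %/% 2)
  hi <- box - 1 + lo
  h <- nrow(px); w <- ncol(px)
  out <- px
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      rr <- max(1, i + lo):min(h, i + hi)
      cc <- max(1, j + lo):min(w, j + hi)
      out[i, j] <- max(px[rr, cc])
    }
  }
  out
}

# Contrastive losses expanded scalar-by-scalar.
oracle_csl <- function(Z, Zc, S, Sc, W, eps = 1e-7) {
  sig <- function(x) 1 / (1 + exp(-x))
  clamp <- function(p) min(max(p, eps), 1 - eps)
  n <- nrow(Z)
  t1 <- t2 <- t3 <- t4 <- 0
  for (i in seq_len(n)) {
    t1 <- t1 + log(clamp(sig(drop(Z[i, ] %*% W %*% S[i, ]))))
    t2 <- t2 + log(1 - clamp(sig(drop(Zc[i, ] %*% W %*% S[i, ]))))
    t3 <- t3 + log(clamp(sig(drop(Zc[i, ] %*% W %*% Sc[i, ]))))
    t4 <- t4 + log(1 - clamp(sig(drop(Z[i, ] %*% W %*% Sc[i, ]))))
  }
  list(csl = -(t1 + t2) / (2 * n), csl_corrupt = -(t3 + t4) / (2 * n))
}

# Normalized dispersion ranking, written independently as plain loops.
oracle_hvg_order <- function(lognorm, n_bins = 20) {
  x <- expm1(lognorm)
  g <- ncol(x)
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ldisp <- log(pmax(disp, .Machine$double.xmin))
  lmu <- log1p(mu)
  bins <- cut(lmu, breaks = n_bins, include.lowest = TRUE)
  nd <- numeric(g)
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (!length(idx)) next
    m <- mean(ldisp[idx])
    s <- if (length(idx) > 1) sd(ldisp[idx]) else 0
    nd[idx] <- if (is.finite(s) && s > 0) (ldisp[idx] - m) / s else ldisp[idx] - m
  }
  order(-nd, seq_len(g))
}

# Fraction of spots agreeing with the modal label of their r nearest spots.
neighbourhood_purity <- function(labels, spots, r = 10) {
  d2 <- as.matrix(dist(cbind(spots$px_row, spots$px_col)))^2
  diag(d2) <- Inf
  n <- length(labels)
  agree <- logical(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(r)]
    counts <- tabulate(labels[nb])
    agree[i] <- labels[i] %in% which(counts == max(counts))
  }
  mean(agree)
}
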