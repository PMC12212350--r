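#' Build the k-nearest-neighbour spot graph
#'
#' Computes the directed kNN relation on Euclidean distance between spot
#' centroids (self excluded; distance ties broken by ascending spot index),
#' then symmetrizes by union — an edge is kept if either endpoint selects the
#' other — so the graph is undirected and every spot has degree >= k. With
#' `k = 6` on a Visium honeycomb the edges recover the hexagonal lattice. The
#' normalized Laplacian is attached via [normalized_laplacian()].
#'
#' @param spots a [spot_table] (or any data frame with `px_row`, `px_col`).
#' @param k number of nearest neighbours (default 6, the hexagonal
#'   neighbourhood).
#' @return a `spatial_graph`: list with sparse binary adjacency `A`, degree
#'   vector `deg`, sparse Laplacian `L = I + D^{-1/2} A D^{-1/2}`, and `k`.
#' @export
build_knn_graph <- function(spots, k = 6L) {
  xy <- cbind(spots$px_row, spots$px_col)
  if (any(!is.finite(xy))) stop("non-finite spot coordinates")
  n <- nrow(xy)
  if (n <= k) stop("need more spots (", n, ") than neighbours k = ", k)
  d2 <- as.matrix(dist(xy))^2
  diag(d2) <- Inf
  idx <- integer(n * k)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))   # stable: ties by ascending index
    idx[((i - 1L) * k + 1L):(i * k)] <- ord[seq_len(k)]
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = idx, x = 1,
                            dims = c(n, n))
  A <- methods::as(((A + Matrix::t(A)) > 0) * 1, "generalMatrix")
  g <- structure(list(A = A, deg = Matrix::rowSums(A), L = NULL, k = as.integer(k)),
                 class = "spatial_graph")
  normalized_laplacian(g)
}

#' Symmetric normalized Laplacian of a spot graph
#'
#' Computes `L = I_N + D^{-1/2} A D^{-1/2}`: the identity plus the
#' degree-normalized adjacency. Note the plus sign — this operator averages a
#' spot with its neighbourhood rather than differencing it, so its spectrum
#' lies in `[0, 2]`; it is the propagation matrix used by the graph
#' convolutional layers.
#'
#' @param g a `spatial_graph` with adjacency `A` and degrees `deg`.
#' @return the graph with `L` filled in (sparse, symmetric, unit diagonal).
#' @export
normalized_laplacian <- function(g) {
  if (any(g$deg == 0)) {
    stop("isolated spot(s) with no neighbours; increase k")
  }
  dn <- Matrix::Diagonal(x = 1 / sqrt(g$deg))
  g$L <- Matrix::Diagonal(length(g$deg)) + dn %*% g$A %*% dn
  g
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d spots, k = %d, %d undirected edges\n",
              nrow(x$A), x$k, sum(x$A) / 2))
  invisible(x)
}

# Row-normalized neighbourhood operator plus self: Q = D^{-1} A + I.
# Q Z gives, per spot, (mean over actual neighbours of Z) + own Z — the
# pre-sigmoid readout. Boundary spots with degree != k average over their
# actual neighbour set.
readout_operator <- function(g) {
  Matrix::Diagonal(x = 1 / g$deg) %*% g$A + Matrix::Diagonal(length(g$deg))
}

#' Export graph edges as a data frame
#'
#' @param g a `spatial_graph`.
#' @return data.frame with columns `from`, `to` (each undirected edge once,
#'   `from < to`).
#' @export
graph_edges <- function(g) {
  tm <- methods::as(Matrix::triu(g$A), "TsparseMatrix")
  data.frame(from = tm@i + 1L, to = tm@j + 1L)
}
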