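#' Extract per-spot image grids
#'
#' Cuts a `d x d` square patch (the grid circumscribing the spot) centred on
#' each spot centroid from every channel, where `d = ceiling(spot diameter in
#' px)`, then resizes each patch to `out_size x out_size` by area-weighted
#' averaging (see [resize_grid()]).
#'
#' @param channels list of [channel_image]s (equal dimensions).
#' @param spots a [spot_table]; pixel coordinates are 0-based.
#' @param out_size output patch side (48 px, a convenient size given Visium
#'   spot diameters of ~100 px or less).
#' @param pad_edges if `TRUE`, patches reaching outside the image are
#'   zero-padded instead of raising an error.
#' @return a `spot_grids` object: list with `grids` (array
#'   `N x C x out x out`), `d`, and `channel_names`.
#' @export
extract_spot_grids <- function(channels, spots, out_size = 48L,
                               pad_edges = FALSE) {
  if (!length(channels)) stop("no image channels supplied")
  d <- as.integer(ceiling(spot_diameter(spots)))
  h <- nrow(channels[[1]]$pixels); w <- ncol(channels[[1]]$pixels)
  n <- nrow(spots); nc <- length(channels)

  # patch rows/cols in 0-based pixel space, centred on the centroid
  r0 <- round(spots$px_row - (d - 1) / 2)
  c0 <- round(spots$px_col - (d - 1) / 2)
  out_of_bounds <- r0 < 0 | c0 < 0 | r0 + d - 1 > h - 1 | c0 + d - 1 > w - 1
  if (any(out_of_bounds) && !pad_edges) {
    stop("spot patch(es) outside image bounds (enable pad_edges to zero-pad): ",
         paste(spots$barcode[out_of_bounds], collapse = ", "))
  }

  rw <- resize_weights(d, out_size)
  grids <- array(0, dim = c(n, nc, out_size, out_size))
  for (ci in seq_len(nc)) {
    px <- channels[[ci]]$pixels
    for (i in seq_len(n)) {
      rows <- r0[i]:(r0[i] + d - 1L)
      cols <- c0[i]:(c0[i] + d - 1L)
      if (out_of_bounds[i]) {
        patch <- matrix(0, d, d)
        rok <- rows >= 0 & rows <= h - 1L
        cok <- cols >= 0 & cols <= w - 1L
        patch[rok, cok] <- px[rows[rok] + 1L, cols[cok] + 1L]
      } else {
        patch <- px[rows + 1L, cols + 1L]
      }
      grids[i, ci, , ] <- rw %*% patch %*% t(rw)
    }
  }
  structure(list(grids = grids, d = d,
                 channel_names = vapply(channels, function(x) x$channel_name,
                                        character(1))),
            class = "spot_grids")
}

#' @export
print.spot_grids <- function(x, ...) {
  dm <- dim(x$grids)
  cat(sprintf("<spot_grids> %d spots x %d channels x %d x %d (source d = %d)\n",
              dm[1], dm[2], dm[3], dm[4], x$d))
  invisible(x)
}

#' Area-weighted-average image resize
#'
#' Resizes a `d x d` matrix to `out x out` by exact pixel mixing: each output
#' pixel is the average of the source pixels its footprint covers, weighted by
#' fractional overlap (the sliding-window size follows from the side-length
#' ratio `d / out`). Constant images stay constant; when `d` is an integer
#' multiple of `out` this is the plain block mean; `d = out` is the identity.
#'
#' @param grid numeric matrix (square).
#' @param out output side length.
#' @return `out x out` numeric matrix.
#' @export
resize_grid <- function(grid, out = 48L) {
  d <- nrow(grid)
  if (ncol(grid) != d) stop("resize_grid expects a square matrix")
  w <- resize_weights(d, out)
  w %*% grid %*% t(w)
}

# out x d row-weight matrix for 1-D area averaging: entry (i, p) is the
# fraction of output cell i's footprint [i*s, (i+1)*s), s = d/out, covered by
# source pixel p, divided by s.
resize_weights <- function(d, out) {
  s <- d / out
  w <- matrix(0, out, d)
  for (i in seq_len(out)) {
    a <- (i - 1) * s; b <- i * s
    p0 <- floor(a); p1 <- min(ceiling(b), d)
    for (p in p0:(p1 - 1)) {
      ov <- min(b, p + 1) - max(a, p)
      if (ov > 0) w[i, p + 1] <- ov / s
    }
  }
  w
}

#' Rescale image grids to the expression range
#'
#' Affinely maps each channel's pixel values so that the channel's min/max
#' across all spots coincide with the global min/max of the preprocessed
#' (scaled) expression matrix, putting the two modalities on a common scale
#' before model training. A constant channel maps to the midpoint of the
#' target range.
#'
#' @param grids a `spot_grids` object.
#' @param ref the scaled HVG [expr_matrix] (or any matrix-like reference
#'   whose range defines the target).
#' @return the rescaled `spot_grids`.
#' @export
normalize_grids <- function(grids, ref) {
  refv <- if (inherits(ref, "expr_matrix")) ref$values else ref
  target <- range(refv)
  for (ci in seq_len(dim(grids$grids)[2])) {
    ch <- grids$grids[, ci, , ]
    rng <- range(ch)
    if (rng[2] > rng[1]) {
      ch <- (ch - rng[1]) / (rng[2] - rng[1]) * (target[2] - target[1]) + target[1]
    } else {
      ch[] <- mean(target)
    }
    grids$grids[, ci, , ] <- ch
  }
  grids
}

#' CNN autoencoder configuration
#'
#' Architecture and training settings for the per-spot image autoencoder:
#' two 5x5 convolution layers ("same" padding) each followed by ReLU and
#' 2x2/stride-2 average pooling, mirrored by two stride-2 transposed
#' convolutions with ReLU; trained with Adam to minimize the summed squared
#' reconstruction error of the grids.
#'
#' @param kernel_size convolution kernel side (5).
#' @param conv_channels encoder layer widths (two integers); for 48x48 input
#'   the defaults give a `conv_channels[2] x 12 x 12` bottleneck.
#' @param lr Adam learning rate.
#' @param n_iter number of optimizer steps.
#' @param batch_size grids per optimizer step (mini-batch; the full set is
#'   used when it is smaller than this).
#' @param seed integer seed for weight initialization and batch order.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(kernel_size = 5L, conv_channels = c(8L, 16L),
                       lr = 1e-3, n_iter = 800L, batch_size = 64L,
                       seed = 1L) {
  stopifnot(kernel_size == 5L, length(conv_channels) == 2L)
  structure(list(kernel_size = as.integer(kernel_size),
                 conv_channels = as.integer(conv_channels),
                 lr = lr, n_iter = as.integer(n_iter),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "cnn_config")
}

#' Train the CNN autoencoder and extract spot-level image features
#'
#' Trains a small convolutional autoencoder on the (normalized) spot grids —
#' every spot/channel grid is one training sample and all channels share
#' weights — then runs a final forward pass and returns the flattened
#' decoder reconstruction of each grid as that spot/channel's feature vector
#' (the bottleneck activations are retained for diagnostics). Training is
#' deterministic given the config seed.
#'
#' @param grids a `spot_grids` object (normalize first; see
#'   [normalize_grids()]).
#' @param cfg a [cnn_config].
#' @return an `image_features` object: list with `features` (array
#'   `N x C x F`, `F = out^2`), `bottleneck` (matrix `(N*C) x (c2*(out/4)^2)`),
#'   `loss` (per-iteration mean per-grid training loss), `channel_names`.
#' @export
train_cnn_autoencoder <- function(grids, cfg = cnn_config()) {
  dm <- dim(grids$grids)
  n <- dm[1]; nc <- dm[2]; side <- dm[3]
  if (n < 2L) stop("need at least 2 spots to train")
  if (side %% 4L != 0L) stop("grid side must be divisible by 4")
  x <- matrix(aperm(grids$grids, c(3, 4, 2, 1)), nrow = side * side)
  # columns = samples (spot-major, channel within spot); pixel index row-major
  # within a grid is handled C-side; here columns are flattened grids
  x <- t(x)                                    # (N*C) x side^2, row r*W+c order
  storage.mode(x) <- "double"

  set.seed(cfg$seed)
  k <- cfg$kernel_size
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  init <- list(
    K1 = glorot(k * k * 1, c1), b1 = numeric(c1),
    K2 = glorot(k * k * c1, c2), b2 = numeric(c2),
    Kd1 = glorot(c2, k * k * c1), bd1 = numeric(c1),
    Kd2 = glorot(c1, k * k), bd2 = numeric(1)
  )
  ns <- nrow(x)
  bs <- min(cfg$batch_size, ns)
  batch_idx <- matrix(0L, cfg$n_iter, bs)
  for (t in seq_len(cfg$n_iter)) batch_idx[t, ] <- sample.int(ns, bs)

  fit <- cnn_train_cpp(x, side, c1, c2, k, cfg$lr, cfg$n_iter, batch_idx, init)
  if (any(!is.finite(fit$loss))) {
    stop("CNN training loss became non-finite; check grid normalization")
  }
  feats <- array(fit$recon, dim = c(nc, n, side * side))  # samples were spot-major
  feats <- aperm(feats, c(2, 1, 3))
  structure(list(features = feats, bottleneck = fit$bottleneck,
                 loss = as.numeric(fit$loss), weights = fit$weights,
                 channel_names = grids$channel_names, cfg = cfg),
            class = "image_features")
}

#' Forward pass of a trained CNN autoencoder
#'
#' Applies fixed trained weights to a set of grids, returning reconstruction
#' features without further training; the map is a pure function of each
#' grid, so reordering spots reorders the features identically.
#'
#' @param fit an `image_features` object from [train_cnn_autoencoder()].
#' @param grids a `spot_grids` object with the same grid side.
#' @return matrix `(N*C) x F` of reconstruction features.
#' @export
cnn_forward <- function(fit, grids) {
  dm <- dim(grids$grids)
  side <- dm[3]
  x <- t(matrix(aperm(grids$grids, c(3, 4, 2, 1)), nrow = side * side))
  storage.mode(x) <- "double"
  cnn_forward_cpp(x, side, fit$cfg$conv_channels[1], fit$cfg$conv_channels[2],
                  fit$cfg$kernel_size, fit$weights)
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}
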