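#' Remove spots outside the tissue
#'
#' Keeps only spots flagged as in-tissue, preserving order and the row
#' correspondence between the spot table and the expression matrix.
#'
#' @param spots a [spot_table].
#' @param expr the matching [expr_matrix] (same row order).
#' @return list with filtered `spots` and `expr`.
#' @export
filter_spots <- function(spots, expr) {
  if (nrow(spots) != nrow(expr$values)) {
    stop("spots and expression matrix have different numbers of rows")
  }
  keep <- spots$in_tissue
  if (!any(keep)) stop("no in-tissue spots remain after filtering")
  out_spots <- spots[keep, , drop = FALSE]
  attr(out_spots, "spot_diameter_px") <- spot_diameter(spots)
  class(out_spots) <- class(spots)
  list(spots = out_spots, expr = subset_spots_expr(expr, keep))
}

#' Remove mitochondrial, spike-in and rarely expressed genes
#'
#' Drops genes whose name matches any mitochondrial or spike-in prefix, and
#' genes with a nonzero count in fewer than `min_spots` spots (a gene seen in
#' exactly `min_spots` spots is kept).
#'
#' @param expr an [expr_matrix] with raw counts.
#' @param mito_prefixes,spikein_prefixes character vectors of gene-name
#'   prefixes to remove.
#' @param min_spots minimum number of spots with nonzero count.
#' @return the filtered [expr_matrix] (may have zero genes).
#' @export
filter_genes <- function(expr, mito_prefixes = c("MT-", "mt-"),
                         spikein_prefixes = "ERCC", min_spots = 3L) {
  if (expr$stage != "raw") stop("filter_genes expects raw counts")
  prefixes <- c(mito_prefixes, spikein_prefixes)
  drop_prefix <- rep(FALSE, length(expr$gene_names))
  for (p in prefixes) {
    drop_prefix <- drop_prefix | startsWith(expr$gene_names, p)
  }
  n_expressed <- Matrix::colSums(expr$values > 0)
  keep <- !drop_prefix & n_expressed >= min_spots
  subset_genes(expr, keep)
}

#' Library-size normalize, log-transform and scale expression
#'
#' Raw counts are (1) scaled per spot so every spot's total equals the median
#' total count across spots, (2) log(1 + x) transformed, and (3) scaled
#' per gene to zero mean and unit variance, with values exceeding `clip_sd`
#' clipped to `clip_sd`. Clipping is one-sided: only large positive values are
#' clipped. Genes with zero variance scale to all-zero columns so the matrix
#' shape is stable.
#'
#' With `scale = FALSE` only steps (1)-(2) run and the result has stage
#' `"normalized"`; this is the input on which highly variable genes are
#' ranked (see [select_hvgs()]). An already-normalized matrix (stage
#' `"normalized"` or `"hvg"`) is only scaled and clipped.
#'
#' @param expr an [expr_matrix] (stage `"raw"`, `"normalized"` or `"hvg"`).
#' @param clip_sd positive clipping bound in units of standard deviation.
#' @param scale if `FALSE`, stop after library-size normalization and log.
#' @return an [expr_matrix] with dense values, stage `"normalized"` or
#'   `"scaled"`.
#' @export
normalize_expression <- function(expr, clip_sd = 10, scale = TRUE) {
  x <- as.matrix(expr$values)
  if (expr$stage == "raw") {
    totals <- rowSums(x)
    if (any(totals <= 0)) {
      bad <- rownames(x)[totals <= 0] %||% which(totals <= 0)
      stop("spot(s) with zero total count: ", paste(bad, collapse = ", "))
    }
    target <- median(totals)
    x <- log1p(x * (target / totals))
    if (!scale) {
      out <- expr
      out$values <- x
      out$stage <- "normalized"
      return(out)
    }
  } else if (!expr$stage %in% c("normalized", "hvg")) {
    stop("normalize_expression expects stage raw, normalized or hvg")
  }
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  x <- sweep(x, 2, mu, "-")
  nz <- sdev > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, sdev[nz], "/")
  x[, !nz] <- 0
  x[x > clip_sd] <- clip_sd
  out <- expr
  out$values <- x
  out$stage <- "scaled"
  out
}

#' Select highly variable genes
#'
#' Ranks genes by binned normalized dispersion on library-size/log-normalized
#' values and keeps the top `n_top` (all genes if fewer are available). The
#' statistic follows the common single-cell convention: per-gene mean and
#' dispersion (variance/mean) are computed on the de-logged normalized counts,
#' genes are grouped into 20 equal-width bins of log mean, and each gene's log
#' dispersion is z-scored within its bin; bins with a single gene or zero
#' spread fall back to centring only. Ties rank by gene order.
#'
#' @param expr an [expr_matrix] at stage `"normalized"`
#'   (see [normalize_expression()] with `scale = FALSE`).
#' @param n_top number of genes to keep.
#' @param n_bins number of mean bins for dispersion normalization.
#' @return the [expr_matrix] restricted to the selected genes, stage `"hvg"`,
#'   with attribute `hvg_rank` giving the selected columns' original indices
#'   in rank order.
#' @export
select_hvgs <- function(expr, n_top = 3000L, n_bins = 20L) {
  if (expr$stage != "normalized") {
    stop("select_hvgs expects a log-normalized matrix (stage 'normalized')")
  }
  g <- ncol(expr$values)
  if (g <= n_top) {
    out <- subset_genes(expr, seq_len(g), stage = "hvg")
    attr(out, "hvg_rank") <- seq_len(g)
    return(out)
  }
  nd <- normalized_dispersion(as.matrix(expr$values), n_bins = n_bins)
  ord <- order(-nd, seq_len(g))          # ties broken by gene order
  sel <- sort(ord[seq_len(n_top)])
  out <- subset_genes(expr, sel, stage = "hvg")
  attr(out, "hvg_rank") <- ord[seq_len(n_top)]
  out
}

# Binned normalized dispersion on log-normalized values (de-logged internally).
normalized_dispersion <- function(logx, n_bins = 20L) {
  x <- expm1(logx)
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ldisp <- log(pmax(disp, .Machine$double.xmin))
  lmu <- log1p(mu)
  bins <- cut(lmu, breaks = n_bins, include.lowest = TRUE)
  out <- numeric(length(disp))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (!length(idx)) next
    m <- mean(ldisp[idx])
    s <- if (length(idx) > 1) sd(ldisp[idx]) else 0
    out[idx] <- if (is.finite(s) && s > 0) (ldisp[idx] - m) / s else ldisp[idx] - m
  }
  out
}

#' Enhance a sparse protein channel
#'
#' Optional noise-reduction for sparse, pathology-like channels (e.g. a DNA
#' damage or amyloid stain): pixels at or below `mean + sd_mult * sd` are set
#' to zero (strict `>` comparison, so a constant image maps to all zeros) and
#' the survivors are dilated with a sliding maximum filter over a
#' `filter_box` x `filter_box` window. Retained pixels keep their original
#' values. The window for even box sizes extends `floor(box/2)` pixels before
#' and `box - 1 - floor(box/2)` after each pixel; at image borders the window
#' is truncated.
#'
#' @param img a [channel_image] (single grayscale channel).
#' @param sd_mult threshold in standard deviations above the mean.
#' @param filter_box side of the square maximum-filter window.
#' @return the enhanced [channel_image].
#' @export
enhance_protein_channel <- function(img, sd_mult = 6, filter_box = 10L) {
  px <- img$pixels
  if (any(!is.finite(px))) stop("non-finite pixel values in channel ",
                                img$channel_name)
  thr <- mean(px) + sd_mult * sd(px)
  px[!(px > thr)] <- 0
  px <- windowed_max(px, filter_box)
  channel_image(px, img$channel_name)
}

# Separable sliding maximum over a box x box window (row pass then column
# pass); borders truncate the window.
windowed_max <- function(px, box) {
  box <- as.integer(box)
  if (box <= 1L) return(px)
  lo <- -(box %/% 2L)
  hi <- box - 1L + lo
  px <- directional_max(px, lo, hi, along_rows = TRUE)
  directional_max(px, lo, hi, along_rows = FALSE)
}

directional_max <- function(px, lo, hi, along_rows) {
  n <- if (along_rows) nrow(px) else ncol(px)
  out <- matrix(-Inf, nrow(px), ncol(px))
  for (s in lo:hi) {
    src <- seq_len(n) + s
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    if (along_rows) {
      out[ok, ] <- pmax(out[ok, , drop = FALSE], px[src[ok], , drop = FALSE])
    } else {
      out[, ok] <- pmax(out[, ok, drop = FALSE], px[, src[ok], drop = FALSE])
    }
  }
  out
}
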