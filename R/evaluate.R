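#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table of co-occurrence counts by the pair-counting formula
#' (sum over cells of `choose(n_ls, 2)` minus its expectation under
#' independent margins, over the corresponding maximum). Invariant to label
#' permutation; 1 iff the partitions are identical up to relabelling; can be
#' negative for agreement below chance. If both partitions are a single
#' cluster the index is 1 by convention (the formula is 0/0 there).
#'
#' @param pred,truth label vectors of equal length (any atomic type).
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("label vectors have different lengths")
  }
  n <- length(pred)
  if (n < 2L) stop("need at least 2 observations")
  tab <- table(pred, truth)
  sum_cells <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  denom <- max_index - expected
  if (abs(denom) < .Machine$double.eps * max(1, max_index)) return(1)
  (sum_cells - expected) / denom
}

#' Mean silhouette width
#'
#' Mean over spots of `(b - a) / max(a, b)` with Euclidean distances, where
#' `a` is the mean within-cluster distance and `b` the smallest mean
#' distance to another cluster. Spots in singleton clusters contribute 0, as
#' do degenerate spots with `a = b = 0`.
#'
#' @param profile numeric matrix (spots in rows), e.g. a `hybrid_profile`.
#' @param labels a `domain_labels` or integer vector; at least two distinct
#'   labels, every cluster nonempty.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(profile, labels) {
  lab <- if (inherits(labels, "domain_labels")) labels$raw else as.integer(labels)
  if (length(unique(lab)) < 2L) {
    stop("silhouette needs at least two clusters")
  }
  sil <- cluster::silhouette(lab, dist(as.matrix(profile)))
  w <- sil[, "sil_width"]
  w[is.nan(w)] <- 0
  mean(w)
}

#' Compare a predicted labels CSV against ground truth
#'
#' Joins on barcode and reports the ARI of the raw (and, when present,
#' refined) predictions.
#'
#' @param pred_file CSV with columns `barcode` and `raw_domain` (optionally
#'   `refined_domain`), as written by [write_labels()], or `domain` as in a
#'   truth file.
#' @param truth_file CSV with columns `barcode` and `domain`.
#' @return list with `ari_raw` and (if available) `ari_refined`.
#' @export
evaluate_labels <- function(pred_file, truth_file) {
  pred <- read.csv(pred_file, stringsAsFactors = FALSE)
  truth <- read.csv(truth_file, stringsAsFactors = FALSE)
  if (!"barcode" %in% names(pred) || !"barcode" %in% names(truth)) {
    stop("both files need a 'barcode' column")
  }
  m <- match(pred$barcode, truth$barcode)
  if (anyNA(m)) stop("barcode(s) in predictions absent from truth")
  tr <- truth$domain[m]
  raw_col <- if ("raw_domain" %in% names(pred)) "raw_domain" else "domain"
  out <- list(ari_raw = adjusted_rand_index(pred[[raw_col]], tr))
  if ("refined_domain" %in% names(pred)) {
    out$ari_refined <- adjusted_rand_index(pred$refined_domain, tr)
  }
  out
}
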