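#' Build the hybrid expression/image profile
#'
#' Runs PCA separately on the reconstructed expression matrix and the
#' reconstructed image features (flattened over channels), takes the top
#' components of each block — a fixed count, or the smallest count reaching a
#' requested variance fraction — and concatenates them, expression block
#' first. The per-block component counts weight the modalities for the
#' downstream clustering: more image components give the image channels more
#' influence.
#'
#' @param H_gene reconstructed expression matrix (`N x F_g`), e.g.
#'   `train_modality(...)$H`.
#' @param H_image reconstructed image features: `N x C x F` array (from
#'   [train_cnn_autoencoder()]-style features passed through the graph
#'   autoencoder) or an `N x F_i` matrix; `NULL` for an expression-only
#'   profile.
#' @param p_gene,p_image number of principal components per block.
#' @param var_gene,var_image alternatively, per-block variance fractions in
#'   (0, 1]; when given they override the fixed counts.
#' @return a `hybrid_profile` matrix (`N x (p_g + p_i)`) with attributes
#'   `block` (column block labels) and `variance_explained`.
#' @export
build_hybrid_profile <- function(H_gene, H_image = NULL, p_gene = 30L,
                                 p_image = 5L, var_gene = NULL,
                                 var_image = NULL) {
  g <- block_pcs(as.matrix(H_gene), p_gene, var_gene, "expression")
  if (is.null(H_image)) {
    out <- g$scores
    attr(out, "block") <- rep("gene", ncol(out))
    attr(out, "variance_explained") <- list(gene = g$varexp)
    class(out) <- c("hybrid_profile", class(out))
    return(out)
  }
  im <- H_image
  if (length(dim(im)) == 3L) {
    im <- matrix(im, nrow = dim(im)[1])   # flatten channels x features
  }
  if (nrow(im) != nrow(H_gene)) stop("modality row counts differ")
  i <- block_pcs(as.matrix(im), p_image, var_image, "image")
  out <- cbind(g$scores, i$scores)
  attr(out, "block") <- rep(c("gene", "image"), c(ncol(g$scores), ncol(i$scores)))
  attr(out, "variance_explained") <- list(gene = g$varexp, image = i$varexp)
  class(out) <- c("hybrid_profile", class(out))
  out
}

block_pcs <- function(x, p, var_target, label) {
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-9)
  if (!is.null(var_target)) {
    stopifnot(var_target > 0, var_target <= 1)
    p <- which(cumsum(ve) >= var_target - 1e-12)[1]
    p <- min(p, rank)
  } else if (p > rank) {
    stop(label, " block: requested ", p, " components but attainable rank is ",
         rank)
  }
  list(scores = pc$x[, seq_len(p), drop = FALSE], varexp = ve[seq_len(p)])
}

#' Model-based clustering of the hybrid profile
#'
#' Fits a Gaussian mixture with shared (EEE) covariance across components via
#' \code{mclust} and returns hard MAP labels. mclust's model-based
#' agglomerative initialization is deterministic, so repeated runs on the
#' same profile give identical labels; the `seed` argument is accepted for
#' interface stability but the backend does not consume randomness.
#'
#' @param profile a `hybrid_profile` (or any numeric matrix, spots in rows).
#' @param k_domains number of domains (>= 2, < number of spots).
#' @param seed unused by the deterministic backend; kept for call-site
#'   compatibility.
#' @param model_names mclust covariance family (default shared full
#'   covariance, `"EEE"`).
#' @return a `domain_labels` list: `raw` (integer labels in `1..k_domains`),
#'   `refined` (`NULL` until [refine_labels()]), `k_domains`, `loglik`.
#' @importFrom mclust Mclust mclustBIC hc hcVVV hcEII hcEEE
#' @export
cluster_domains <- function(profile, k_domains, seed = NULL,
                            model_names = "EEE") {
  n <- nrow(profile)
  if (k_domains < 2L) stop("k_domains must be >= 2")
  if (k_domains >= n) stop("k_domains must be smaller than the number of spots")
  x <- as.matrix(profile)
  dimnames(x) <- NULL
  fit <- mclust::Mclust(x, G = k_domains, modelNames = model_names,
                        verbose = FALSE,
                        initialization = list(hcPairs = mclust::hc(x)))
  if (is.null(fit)) stop("mixture fit failed for k = ", k_domains)
  structure(list(raw = as.integer(fit$classification), refined = NULL,
                 k_domains = as.integer(k_domains), loglik = fit$loglik),
            class = "domain_labels")
}

#' @export
print.domain_labels <- function(x, ...) {
  cat(sprintf("<domain_labels> %d spots, k = %d%s\n", length(x$raw),
              x$k_domains,
              if (!is.null(x$refined)) " (refined)" else ""))
  invisible(x)
}

#' Choose the number of domains by silhouette
#'
#' Fits [cluster_domains()] for every `k` in `k_range`, scores each labelling
#' by the mean silhouette width on the hybrid profile (Euclidean distance),
#' and returns the `k` with the highest score; ties go to the smallest `k`.
#'
#' @param profile a `hybrid_profile`.
#' @param k_range integer vector of candidate domain counts.
#' @param seed passed through to [cluster_domains()].
#' @return the selected `k`, with the score table as attribute `scores`.
#' @export
choose_k_by_silhouette <- function(profile, k_range = 2:8, seed = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2L), all(k_range < nrow(profile)))
  sc <- vapply(k_range, function(k) {
    lab <- cluster_domains(profile, k, seed = seed)
    silhouette_score(profile, lab)
  }, numeric(1))
  out <- k_range[which.max(sc)]   # first max = smallest k on ties
  attr(out, "scores") <- data.frame(k = k_range, silhouette = sc)
  out
}

#' Spatially refine domain labels
#'
#' One pass of neighbourhood majority voting: every spot is relabelled to the
#' most common raw label among its `r` nearest other spots (Euclidean
#' distance between centroids, self excluded, distance ties broken by spot
#' index). All votes read the pre-refinement labels, so there is no
#' cascading. On a tied vote the spot keeps its own raw label if it is among
#' the tied modes, otherwise the smallest tied label wins. Refinement never
#' invents a label absent from the raw labels.
#'
#' @param labels a `domain_labels` (or bare integer vector).
#' @param spots the matching [spot_table].
#' @param r neighbourhood size.
#' @return the `domain_labels` with `refined` filled in.
#' @export
refine_labels <- function(labels, spots, r = 10L) {
  raw <- if (inherits(labels, "domain_labels")) labels$raw else as.integer(labels)
  n <- length(raw)
  if (n != nrow(spots)) stop("labels and spots have different lengths")
  if (r >= n) stop("r must be smaller than the number of spots")
  d2 <- as.matrix(dist(cbind(spots$px_row, spots$px_col)))^2
  diag(d2) <- Inf
  refined <- integer(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ], seq_len(n))[seq_len(r)]
    counts <- tabulate(raw[nb])
    best <- which(counts == max(counts))
    refined[i] <- if (raw[i] %in% best) raw[i] else min(best)
  }
  if (inherits(labels, "domain_labels")) {
    labels$refined <- refined
    labels$r <- as.integer(r)
    labels
  } else {
    structure(list(raw = raw, refined = refined,
                   k_domains = max(raw), r = as.integer(r)),
              class = "domain_labels")
  }
}
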