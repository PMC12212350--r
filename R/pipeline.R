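#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. Defaults follow the
#' method's standard settings: 3000 highly variable genes, scaling clipped at
#' +10 SD, k = 6 spatial neighbours, 800 CNN and 600 GCN iterations at
#' learning rate 1e-3, 30 expression + 5 image principal components,
#' refinement neighbourhood r = 10.
#'
#' @param visium_dir input directory for [load_visium()].
#' @param image path to the image TIFF (`NULL` for expression-only runs).
#' @param output_dir where artifacts are written (`NULL` to skip writing).
#' @param channels_used names of image channels to use; `NULL` = all,
#'   `character(0)` = none (expression-only run).
#' @param enhance_channels names of channels to pass through
#'   [enhance_protein_channel()] (sparse pathology-like stains).
#' @param sd_mult,filter_box enhancement parameters.
#' @param n_hvg,clip_sd expression preprocessing parameters.
#' @param mito_prefixes,spikein_prefixes,min_spots gene filtering parameters.
#' @param k spatial graph neighbour count.
#' @param cnn a [cnn_config] (its seed is overridden by `seed`).
#' @param gcn_expression,gcn_image [gcn_config]s per modality (seeds
#'   overridden by `seed`).
#' @param p_gene,p_image,var_gene,var_image hybrid-profile weights.
#' @param k_domains fixed number of domains, or `NULL` to select by
#'   silhouette over `k_range`.
#' @param k_range candidate domain counts when `k_domains` is `NULL`.
#' @param r refinement neighbourhood size.
#' @param truth CSV of ground-truth labels (barcode, domain) for evaluation,
#'   or `NULL`.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(visium_dir, image = NULL, output_dir = NULL,
                       channels_used = NULL, enhance_channels = character(0),
                       sd_mult = 6, filter_box = 10L,
                       n_hvg = 3000L, clip_sd = 10,
                       mito_prefixes = c("MT-", "mt-"),
                       spikein_prefixes = "ERCC", min_spots = 3L,
                       k = 6L,
                       cnn = cnn_config(), gcn_expression = gcn_config(),
                       gcn_image = gcn_config(),
                       p_gene = 30L, p_image = 5L,
                       var_gene = NULL, var_image = NULL,
                       k_domains = NULL, k_range = 2:8, r = 10L,
                       truth = NULL, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file is a flat, commented key-value document whose keys mirror the
#' [run_config()] arguments; nested `cnn`/`gcn_*` blocks override individual
#' fields of the corresponding configs.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$visium_dir)) stop("config must set visium_dir")
  args <- y
  for (nm in c("cnn", "gcn_expression", "gcn_image")) {
    if (!is.null(y[[nm]])) {
      base <- if (nm == "cnn") cnn_config() else gcn_config()
      for (f in names(y[[nm]])) base[[f]] <- y[[nm]][[f]]
      args[[nm]] <- base
    }
  }
  if (!is.null(args$channels_used)) {
    args$channels_used <- as.character(args$channels_used)
  }
  do.call(run_config, args)
}

#' Run the full domain-detection pipeline
#'
#' Executes load, spot/gene filtering, normalization, HVG selection, optional
#' channel enhancement, patch extraction and CNN feature learning, spatial
#' graph construction, per-modality graph autoencoder training with
#' contrastive refinement, hybrid-profile PCA fusion, mixture clustering,
#' spatial refinement, and evaluation. When `output_dir` is set, writes
#' `labels.csv` (barcode, raw_domain, refined_domain), `metrics.json`,
#' per-stage training-curve CSVs, the hybrid profile as TSV, and a
#' `config_echo.yaml` with the seed and package version. Stage failures are
#' reported with the stage name. Deterministic given the config and seed.
#'
#' @param cfg a [run_config], or the path to a YAML config file.
#' @return a `pipeline_result`: list with `spots`, `labels`
#'   (`domain_labels`), `profile`, `metrics`, `embeddings` (per modality),
#'   `cnn` (image feature fit or `NULL`), `config`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  dat <- stage("load", load_visium(cfg$visium_dir, cfg$image))
  fl <- stage("filter_spots", filter_spots(dat$spots, dat$expr))
  spots <- fl$spots
  expr <- stage("filter_genes",
                filter_genes(fl$expr, cfg$mito_prefixes, cfg$spikein_prefixes,
                             cfg$min_spots))
  norm <- stage("normalize", normalize_expression(expr, cfg$clip_sd, scale = FALSE))
  hvg <- stage("select_hvgs", select_hvgs(norm, cfg$n_hvg))
  scaled <- stage("scale", normalize_expression(hvg, cfg$clip_sd))

  channels <- dat$channels
  if (!is.null(cfg$channels_used)) {
    keep <- vapply(channels, function(ch) ch$channel_name %in% cfg$channels_used,
                   logical(1))
    channels <- channels[keep]
  }
  use_image <- length(channels) > 0L

  cnn_fit <- NULL
  img_embed <- NULL
  g <- stage("graph", build_knn_graph(spots, cfg$k))

  if (use_image) {
    for (i in seq_along(channels)) {
      if (channels[[i]]$channel_name %in% cfg$enhance_channels) {
        channels[[i]] <- stage("enhance",
                               enhance_protein_channel(channels[[i]],
                                                       cfg$sd_mult,
                                                       cfg$filter_box))
      }
    }
    grids <- stage("grids", extract_spot_grids(channels, spots))
    grids <- stage("normalize_grids", normalize_grids(grids, scaled))
    cnn_cfg <- cfg$cnn; cnn_cfg$seed <- cfg$seed + 101L
    cnn_fit <- stage("cnn", train_cnn_autoencoder(grids, cnn_cfg))
    img_x <- matrix(cnn_fit$features, nrow = dim(cnn_fit$features)[1])
    gcn_i <- cfg$gcn_image; gcn_i$seed <- cfg$seed + 303L
    img_embed <- stage("gcn_image",
                       train_modality(img_x, g, gcn_i, modality = "image"))
  }

  gcn_e <- cfg$gcn_expression; gcn_e$seed <- cfg$seed + 202L
  expr_embed <- stage("gcn_expression",
                      train_modality(scaled$values, g, gcn_e,
                                     modality = "expression"))

  profile <- stage("hybrid_profile",
                   build_hybrid_profile(expr_embed$H,
                                        if (use_image) img_embed$H else NULL,
                                        p_gene = cfg$p_gene,
                                        p_image = cfg$p_image,
                                        var_gene = cfg$var_gene,
                                        var_image = cfg$var_image))

  k_dom <- cfg$k_domains
  if (is.null(k_dom)) {
    k_dom <- stage("choose_k",
                   as.integer(choose_k_by_silhouette(profile, cfg$k_range,
                                                     seed = cfg$seed)))
  }
  labels <- stage("cluster", cluster_domains(profile, k_dom, seed = cfg$seed))
  labels <- stage("refine", refine_labels(labels, spots, cfg$r))

  metrics <- list(
    silhouette = silhouette_score(profile, labels),
    k_domains = k_dom,
    n_spots = nrow(spots)
  )
  if (!is.null(cfg$truth)) {
    truth <- read.csv(cfg$truth, stringsAsFactors = FALSE)
    tr <- truth$domain[match(spots$barcode, truth$barcode)]
    if (anyNA(tr)) stop("pipeline stage 'evaluate': truth is missing barcodes")
    metrics$ari_raw <- adjusted_rand_index(labels$raw, tr)
    metrics$ari_refined <- adjusted_rand_index(labels$refined, tr)
  }

  result <- structure(list(spots = spots, labels = labels, profile = profile,
                           metrics = metrics,
                           embeddings = list(expression = expr_embed,
                                             image = img_embed),
                           cnn = cnn_fit, config = cfg),
                      class = "pipeline_result")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_labels(labels, spots, file.path(cfg$output_dir, "labels.csv"))
    jsonlite::write_json(metrics, file.path(cfg$output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(expr_embed$losses,
              file.path(cfg$output_dir, "gcn_expression_losses.csv"),
              row.names = FALSE)
    if (use_image) {
      write.csv(img_embed$losses,
                file.path(cfg$output_dir, "gcn_image_losses.csv"),
                row.names = FALSE)
      write.csv(data.frame(iter = seq_along(cnn_fit$loss), loss = cnn_fit$loss),
                file.path(cfg$output_dir, "cnn_losses.csv"), row.names = FALSE)
    }
    prof_out <- data.frame(barcode = spots$barcode, unclass(profile))
    write.table(prof_out, file.path(cfg$output_dir, "hybrid_profile.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    echo <- cfg
    echo$cnn <- unclass(echo$cnn); echo$gcn_expression <- unclass(echo$gcn_expression)
    echo$gcn_image <- unclass(echo$gcn_image)
    echo <- c(unclass(echo),
              list(package_version = as.character(utils::packageVersion("spotfuse"))))
    yaml::write_yaml(echo, file.path(cfg$output_dir, "config_echo.yaml"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d spots, k = %d domains, silhouette %.3f\n",
              x$metrics$n_spots, x$metrics$k_domains, x$metrics$silhouette))
  if (!is.null(x$metrics$ari_refined)) {
    cat(sprintf("  ARI vs truth: raw %.3f, refined %.3f\n",
                x$metrics$ari_raw, x$metrics$ari_refined))
  }
  invisible(x)
}
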