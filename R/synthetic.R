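#' Configuration for the synthetic Visium-like generator
#'
#' Describes a single synthetic tissue section: a honeycomb spot lattice
#' carved into ground-truth domains, a negative-binomial count matrix with
#' planted domain markers, and one or more image channels whose intensity
#' tracks the domains.
#'
#' Defaults emulate a desk-scale section with a clear, but not trivial,
#' spatial signal: a 30 x 30 lattice (900 spots), 3 horizontal-layer domains,
#' 300 genes of which 50 per domain are markers elevated by 2 natural-log
#' units, moderate negative-binomial overdispersion, and one
#' domain-correlated image channel at contrast 0.8 with light Gaussian pixel
#' noise.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param domain_layout `"horizontal_layers"`, `"concentric"` or `"blocks"`.
#' @param n_domains number of ground-truth domains (>= 2).
#' @param n_genes total number of genes.
#' @param n_marker_genes_per_domain markers planted per domain.
#' @param expression_effect natural-log fold elevation of a marker in its
#'   own domain.
#' @param nb_mean_log,nb_mean_sdlog log-normal parameters for per-gene
#'   baseline negative-binomial means.
#' @param nb_size negative-binomial size (inverse overdispersion).
#' @param n_channels number of image channels.
#' @param channel_modes per-channel mode: `"domain_correlated"`, `"spotty"`
#'   or `"uniform"` (recycled to `n_channels`).
#' @param image_domain_contrast domain intensity contrast in `[0, 1]`.
#' @param image_noise_sd Gaussian pixel noise standard deviation (intensity
#'   units, images live in `[0, 1]`).
#' @param seed integer seed; every generator draw derives from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 30L, n_cols = 30L,
                             domain_layout = c("horizontal_layers",
                                               "concentric", "blocks"),
                             n_domains = 3L,
                             n_genes = 300L,
                             n_marker_genes_per_domain = 50L,
                             expression_effect = 2,
                             nb_mean_log = 0, nb_mean_sdlog = 1, nb_size = 2,
                             n_channels = 1L,
                             channel_modes = "domain_correlated",
                             image_domain_contrast = 0.8,
                             image_noise_sd = 0.02,
                             seed = 1L) {
  domain_layout <- match.arg(domain_layout)
  if (n_domains < 2L) stop("n_domains must be >= 2")
  if (n_rows * n_cols < 20L * n_domains) {
    stop("lattice too small: each domain needs >= 20 spots")
  }
  if (n_marker_genes_per_domain * n_domains > n_genes) {
    stop("more planted markers than genes")
  }
  channel_modes <- rep_len(channel_modes, n_channels)
  stopifnot(all(channel_modes %in% c("domain_correlated", "spotty", "uniform")))
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    domain_layout = domain_layout, n_domains = as.integer(n_domains),
    n_genes = as.integer(n_genes),
    n_marker_genes_per_domain = as.integer(n_marker_genes_per_domain),
    expression_effect = expression_effect,
    nb_mean_log = nb_mean_log, nb_mean_sdlog = nb_mean_sdlog,
    nb_size = nb_size,
    n_channels = as.integer(n_channels), channel_modes = channel_modes,
    image_domain_contrast = image_domain_contrast,
    image_noise_sd = image_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Lattice geometry: 100 px pitch within a row, odd rows shifted half a pitch,
# 87 px between rows (integer-pixel honeycomb approximation of the regular
# row spacing 100 * sqrt(3)/2 = 86.6), so each interior spot's six lattice
# neighbours are its nearest neighbours with a wide margin to the second
# shell. A 100 px margin keeps every spot patch inside the image.
HONEYCOMB_PITCH <- 100
HONEYCOMB_ROW_STEP <- 87
HONEYCOMB_MARGIN <- 100

#' Honeycomb spot lattice
#'
#' Builds the Visium-style spot arrangement: spots 100 px apart
#' centre-to-centre within a row, alternate rows offset by half a pitch, so
#' each interior spot is surrounded by six near-equidistant neighbours. All
#' spots are flagged in-tissue; the spot diameter is 55 px (0.55 x pitch).
#' Pixel coordinates are integers, which makes fixture round trips through
#' disk exact. The construction is deterministic.
#'
#' @param config a [synthetic_config].
#' @return a [spot_table] with `n_rows * n_cols` spots.
#' @export
make_honeycomb <- function(config) {
  rows <- rep(seq_len(config$n_rows) - 1L, each = config$n_cols)
  cols <- rep(seq_len(config$n_cols) - 1L, times = config$n_rows)
  px_row <- HONEYCOMB_MARGIN + rows * HONEYCOMB_ROW_STEP
  px_col <- HONEYCOMB_MARGIN + cols * HONEYCOMB_PITCH +
    (rows %% 2L) * (HONEYCOMB_PITCH / 2)
  n <- length(rows)
  spot_table(
    barcode = sprintf("SPOT-%05d-1", seq_len(n)),
    in_tissue = rep(TRUE, n),
    array_row = rows, array_col = cols,
    px_row = px_row, px_col = px_col,
    spot_diameter_px = 0.55 * HONEYCOMB_PITCH
  )
}

#' Ground-truth domain labels for a lattice
#'
#' Assigns each spot to one of `n_domains` domains according to the layout:
#' `horizontal_layers` slices the lattice into equal bands of rows,
#' `concentric` uses equal-count quantiles of distance from the section
#' centre, and `blocks` tiles the lattice into a near-square grid of blocks.
#'
#' @param spots a [spot_table] (typically from [make_honeycomb()]).
#' @param config a [synthetic_config].
#' @return integer vector of labels in `1..n_domains`.
#' @export
make_domains <- function(spots, config) {
  k <- config$n_domains
  switch(config$domain_layout,
    horizontal_layers = {
      nr <- max(spots$array_row) + 1L
      pmin(k, 1L + (spots$array_row * k) %/% nr)
    },
    concentric = {
      d <- sqrt((spots$px_row - mean(spots$px_row))^2 +
                (spots$px_col - mean(spots$px_col))^2)
      qs <- quantile(d, probs = seq_len(k - 1L) / k)
      1L + rowSums(outer(d, qs, ">"))
    },
    blocks = {
      br <- max(1L, floor(sqrt(k)))
      bc <- ceiling(k / br)
      nr <- max(spots$array_row) + 1L
      nc <- max(spots$array_col) + 1L
      rb <- (spots$array_row * br) %/% nr
      cb <- (spots$array_col * bc) %/% nc
      pmin(k, 1L + rb * bc + cb)
    })
}

#' Simulate a domain-structured count matrix
#'
#' Draws negative-binomial counts with per-gene baseline means sampled
#' log-normally; the first `n_domains * n_marker_genes_per_domain` genes are
#' markers, each elevated by `exp(expression_effect)` in its assigned domain.
#' Fully reproducible under the config seed.
#'
#' @param spots a [spot_table].
#' @param labels integer domain labels, one per spot.
#' @param config a [synthetic_config].
#' @return an [expr_matrix] (stage `"raw"`, sparse values) with attribute
#'   `marker_domain` (integer per gene, `NA` for background genes).
#' @export
simulate_expression <- function(spots, labels, config) {
  n <- nrow(spots)
  if (length(labels) != n) stop("labels must have one entry per spot")
  g <- config$n_genes
  set.seed(config$seed + 1L)
  base_mu <- exp(rnorm(g, config$nb_mean_log, config$nb_mean_sdlog))
  marker_domain <- rep(NA_integer_, g)
  n_mark <- config$n_marker_genes_per_domain
  if (n_mark > 0) {
    marker_domain[seq_len(config$n_domains * n_mark)] <-
      rep(seq_len(config$n_domains), each = n_mark)
  }
  mu <- matrix(base_mu, n, g, byrow = TRUE)
  boost <- exp(config$expression_effect)
  for (j in which(!is.na(marker_domain))) {
    in_dom <- labels == marker_domain[j]
    mu[in_dom, j] <- mu[in_dom, j] * boost
  }
  counts <- matrix(rnbinom(n * g, size = config$nb_size, mu = mu), n, g)
  vals <- Matrix::Matrix(counts, sparse = TRUE)
  rownames(vals) <- spots$barcode
  out <- expr_matrix(vals, gene_ids = sprintf("ENSG%05d", seq_len(g)),
                     gene_names = sprintf("GENE%04d", seq_len(g)),
                     stage = "raw")
  attr(out, "marker_domain") <- marker_domain
  out
}

#' Simulate image channels over the lattice
#'
#' Paints one image per channel at full resolution. `domain_correlated`
#' channels give every domain a distinct base intensity, shrunk towards the
#' mid-grey 0.55 by `1 - image_domain_contrast`; each spot's 100 x 100 px
#' cell is painted with its domain's intensity. `spotty` channels place
#' isolated bright blobs inside domain 1 only (mimicking a sparsely
#' distributed pathology stain). `uniform` channels are mid-grey. Gaussian
#' noise of sd `image_noise_sd` is added everywhere and intensities are
#' clipped to `[0, 1]`. Reproducible under the config seed.
#'
#' @param spots a [spot_table].
#' @param labels integer domain labels, one per spot.
#' @param config a [synthetic_config].
#' @return list of [channel_image]s named `CH1..CHn`.
#' @export
simulate_images <- function(spots, labels, config) {
  n <- nrow(spots)
  if (length(labels) != n) stop("labels must have one entry per spot")
  h <- as.integer(max(spots$px_row) + HONEYCOMB_MARGIN + 1L)
  w <- as.integer(max(spots$px_col) + HONEYCOMB_MARGIN + 1L)
  k <- config$n_domains
  mid <- 0.55
  base <- if (k > 1) 0.2 + 0.7 * (seq_len(k) - 1) / (k - 1) else mid
  dom_val <- mid + config$image_domain_contrast * (base - mid)
  half <- HONEYCOMB_PITCH / 2

  set.seed(config$seed + 2L)
  channels <- vector("list", config$n_channels)
  for (ci in seq_len(config$n_channels)) {
    mode <- config$channel_modes[ci]
    px <- matrix(0, h, w)
    if (mode == "domain_correlated") {
      for (i in seq_len(n)) {
        r <- (spots$px_row[i] - half):(spots$px_row[i] + half) + 1L
        cc <- (spots$px_col[i] - half):(spots$px_col[i] + half) + 1L
        r <- r[r >= 1 & r <= h]; cc <- cc[cc >= 1 & cc <= w]
        px[r, cc] <- dom_val[labels[i]]
      }
    } else if (mode == "uniform") {
      px[] <- mid
    } else { # spotty: isolated bright blobs inside domain 1
      hosts <- which(labels == 1L)
      n_blobs <- max(5L, length(hosts) %/% 5L)
      chosen <- sample(hosts, n_blobs, replace = TRUE)
      for (i in chosen) {
        br <- spots$px_row[i] + sample(-20:20, 1)
        bc <- spots$px_col[i] + sample(-20:20, 1)
        rr <- max(1, br - 3):min(h, br + 3)
        cc <- max(1, bc - 3):min(w, bc + 3)
        px[rr, cc] <- 1
      }
    }
    if (config$image_noise_sd > 0) {
      px <- px + matrix(rnorm(h * w, 0, config$image_noise_sd), h, w)
    }
    px[px < 0] <- 0; px[px > 1] <- 1
    channels[[ci]] <- channel_image(px, paste0("CH", ci))
  }
  channels
}

#' Write a complete synthetic Visium-style fixture to disk
#'
#' Generates lattice, domains, counts and images for `config` and writes a
#' directory that [load_visium()] accepts: MatrixMarket counts with barcode
#' and feature TSVs, a headered tissue-positions CSV, a scale-factors JSON, a
#' multi-page TIFF (16-bit, one page per channel), and a ground-truth
#' `truth_labels.csv` (barcode, domain). Counts and coordinates round-trip
#' exactly.
#'
#' @param config a [synthetic_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory `spots`, `labels`, `expr`,
#'   `channels` and the `dir` and `image` paths.
#' @export
simulate_fixture <- function(config = synthetic_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spots <- make_honeycomb(config)
  labels <- make_domains(spots, config)
  expr <- simulate_expression(spots, labels, config)
  channels <- simulate_images(spots, labels, config)

  Matrix::writeMM(methods::as(Matrix::t(expr$values), "TsparseMatrix"),
                  file.path(out_dir, "matrix.mtx"))
  writeLines(spots$barcode, file.path(out_dir, "barcodes.tsv"))
  write.table(data.frame(expr$gene_ids, expr$gene_names, "Gene Expression"),
              file.path(out_dir, "features.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  pos <- data.frame(barcode = spots$barcode,
                    in_tissue = as.integer(spots$in_tissue),
                    array_row = spots$array_row, array_col = spots$array_col,
                    pxl_row_in_fullres = spots$px_row,
                    pxl_col_in_fullres = spots$px_col)
  write.csv(pos, file.path(out_dir, "tissue_positions.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(spot_diameter_fullres = spot_diameter(spots)),
                       file.path(out_dir, "scalefactors_json.json"),
                       auto_unbox = TRUE, digits = NA)
  image_path <- file.path(out_dir, "image.tiff")
  tiff::writeTIFF(lapply(channels, function(ch) ch$pixels), image_path,
                  bits.per.sample = 16L)
  write.csv(data.frame(barcode = spots$barcode, domain = labels),
            file.path(out_dir, "truth_labels.csv"),
            row.names = FALSE, quote = FALSE)

  invisible(list(spots = spots, labels = labels, expr = expr,
                 channels = channels, dir = out_dir, image = image_path))
}
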