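# Small in-code fixtures shared across test files.

tiny_expr <- function(values, gene_names = NULL, stage = "raw") {
  g <- ncol(values)
  if (is.null(gene_names)) gene_names <- sprintf("GENE%03d", seq_len(g))
  expr_matrix(values, gene_ids = sprintf("ID%03d", seq_len(g)),
              gene_names = gene_names, stage = stage)
}

tiny_spots <- function(px_row, px_col, in_tissue = TRUE, diameter = 55) {
  n <- length(px_row)
  spot_table(barcode = sprintf("BC%04d", seq_len(n)),
             in_tissue = rep_len(in_tissue, n),
             array_row = rep(0L, n), array_col = seq_len(n) - 1L,
             px_row = px_row, px_col = px_col,
             spot_diameter_px = diameter)
}

# A compact synthetic section used by several unit tests (cached per session).
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_rows = 10L, n_cols = 10L, n_domains = 2L,
                              n_genes = 80L, n_marker_genes_per_domain = 15L,
                              seed = 42L)
      spots <- make_honeycomb(cfg)
      labels <- make_domains(spots, cfg)
      cache <<- list(cfg = cfg, spots = spots, labels = labels,
                     expr = simulate_expression(spots, labels, cfg),
                     channels = simulate_images(spots, labels, cfg))
    }
    cache
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
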