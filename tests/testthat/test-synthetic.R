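test_that("honeycomb lattice has hexagonal neighbourhoods and is deterministic", {
  cfg <- synthetic_config(n_rows = 10L, n_cols = 10L, n_domains = 2L,
                          n_genes = 60L, n_marker_genes_per_domain = 10L)
  spots <- make_honeycomb(cfg)
  expect_equal(nrow(spots), 100L)
  expect_true(all(spots$in_tissue))

  # every interior spot: 6 nearest neighbours at (near-)equal distance, with a
  # clear gap to the seventh
  xy <- cbind(spots$px_row, spots$px_col)
  interior <- which(spots$array_row %in% 2:7 & spots$array_col %in% 2:7)
  for (i in interior[c(1, 10, 25)]) {
    d <- sort(sqrt(colSums((t(xy) - xy[i, ])^2)))[-1]
    expect_lt(d[6] / d[1], 1.01)       # six equidistant up to lattice rounding
    expect_gt(d[7] / d[6], 1.5)        # second shell is far away
  }
  expect_identical(make_honeycomb(cfg), spots)

  two <- make_honeycomb(synthetic_config(n_rows = 5L, n_cols = 8L,
                                         n_domains = 2L, n_genes = 60L,
                                         n_marker_genes_per_domain = 10L))
  expect_equal(nrow(two), 40L)
})

test_that("domain layouts cover the requested labels with enough spots", {
  for (layout in c("horizontal_layers", "concentric", "blocks")) {
    cfg <- synthetic_config(n_rows = 12L, n_cols = 12L, n_domains = 3L,
                            domain_layout = layout, n_genes = 60L,
                            n_marker_genes_per_domain = 10L)
    labels <- make_domains(make_honeycomb(cfg), cfg)
    expect_setequal(unique(labels), 1:3)
    expect_true(all(table(labels) >= 20))
  }
})

test_that("planted markers are recoverable and the null case is flat", {
  fx <- small_fixture()
  cfg <- fx$cfg
  expr <- fx$expr
  md <- attr(expr, "marker_domain")
  counts <- as.matrix(expr$values)

  # naive per-gene mean-difference ranking recovers planted markers
  in1 <- fx$labels == 1L
  delta <- abs(colMeans(counts[in1, ]) - colMeans(counts[!in1, ])) /
    (colMeans(counts) + 1)
  n_markers <- sum(!is.na(md))
  top <- order(-delta)[seq_len(n_markers)]
  recovered <- mean(top %in% which(!is.na(md)))
  expect_gte(recovered, 0.9)

  # zero effect: marker means equal across domains within sampling error
  cfg0 <- fx$cfg; cfg0$expression_effect <- 0
  expr0 <- simulate_expression(fx$spots, fx$labels, cfg0)
  c0 <- as.matrix(expr0$values)
  m1 <- mean(c0[in1, 1:15]); m2 <- mean(c0[!in1, 1:15])
  expect_lt(abs(m1 - m2) / m1, 0.15)

  # determinism
  expect_identical(as.matrix(simulate_expression(fx$spots, fx$labels, cfg)$values),
                   counts)
})

test_that("image channels encode domains at the configured contrast", {
  fx <- small_fixture()
  cfg <- fx$cfg

  # exact patch intensity at full contrast, zero noise
  cfg1 <- cfg; cfg1$image_domain_contrast <- 1; cfg1$image_noise_sd <- 0
  ch <- simulate_images(fx$spots, fx$labels, cfg1)[[1]]
  grids <- extract_spot_grids(list(ch), fx$spots)
  base <- c(0.2, 0.9)
  for (i in c(1, 55, 100)) {
    expect_equal(mean(grids$grids[i, 1, , ]), base[fx$labels[i]],
                 tolerance = 1e-12)
  }

  # zero contrast: per-domain mean intensities agree within noise
  cfg0 <- cfg; cfg0$image_domain_contrast <- 0
  ch0 <- simulate_images(fx$spots, fx$labels, cfg0)[[1]]
  g0 <- extract_spot_grids(list(ch0), fx$spots)
  mu <- vapply(1:2, function(d) mean(g0$grids[fx$labels == d, 1, , ]), numeric(1))
  expect_lt(abs(mu[1] - mu[2]), 0.01)

  # spotty channel is sparse: almost all pixels below mean + 2 sd
  cfgs <- cfg; cfgs$channel_modes <- "spotty"
  chs <- simulate_images(fx$spots, fx$labels, cfgs)[[1]]$pixels
  frac <- mean(chs < mean(chs) + 2 * sd(chs))
  expect_gte(frac, 0.95)

  # determinism
  expect_identical(simulate_images(fx$spots, fx$labels, cfg)[[1]]$pixels,
                   fx$channels[[1]]$pixels)
})
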