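#' Load a Visium-style directory and its paired image
#'
#' Reads the standard spaceranger-style outputs for one tissue section: a
#' MatrixMarket count matrix with barcode and feature TSVs, a tissue-positions
#' table (either the headered dialect or the 6-column headerless legacy
#' dialect), a scale-factors JSON holding the full-resolution spot diameter,
#' and a TIFF image. A multi-page TIFF is returned as one [channel_image] per
#' page; an RGB image is split into three channel images named `R`, `G`, `B`.
#'
#' Spots are returned in the order of the barcodes file, and the positions
#' table is re-ordered to match, so the [spot_table] and [expr_matrix] rows
#' correspond one-to-one. No filtering is applied here.
#'
#' @param path directory containing `matrix.mtx(.gz)`, `barcodes.tsv(.gz)`,
#'   `features.tsv(.gz)`, `tissue_positions.csv` (or
#'   `tissue_positions_list.csv`) and `scalefactors_json.json`.
#' @param image_path path to a TIFF image; `NULL` to skip image loading.
#' @param channel_names optional character vector naming the image channels;
#'   defaults to `R`,`G`,`B` for RGB images and `CH1..CHn` otherwise.
#' @return list with elements `spots` ([spot_table]), `expr` ([expr_matrix],
#'   stage `"raw"`), and `channels` (list of [channel_image], possibly empty).
#' @export
load_visium <- function(path, image_path = NULL, channel_names = NULL) {
  mtx <- find_input_file(path, c("matrix.mtx", "matrix.mtx.gz"))
  bcf <- find_input_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  ftf <- find_input_file(path, c("features.tsv", "features.tsv.gz",
                                 "genes.tsv", "genes.tsv.gz"))
  posf <- find_input_file(path, c("tissue_positions.csv",
                                  "tissue_positions_list.csv"))
  sff <- find_input_file(path, c("scalefactors_json.json"))

  counts <- Matrix::readMM(mtx)          # features x barcodes (vendor layout)
  barcodes <- read.delim(bcf, header = FALSE, stringsAsFactors = FALSE)[[1]]
  feats <- read.delim(ftf, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(counts) != length(barcodes)) {
    stop("barcode count (", length(barcodes), ") does not match matrix columns (",
         ncol(counts), ") in ", path)
  }
  if (nrow(counts) != nrow(feats)) {
    stop("feature count does not match matrix rows in ", path)
  }
  gene_ids <- feats[[1]]
  gene_names <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]

  pos <- read_tissue_positions(posf)
  if (!setequal(pos$barcode, barcodes)) {
    missing_in_counts <- setdiff(pos$barcode, barcodes)
    missing_in_pos <- setdiff(barcodes, pos$barcode)
    stop("barcode mismatch between counts and positions: ",
         length(missing_in_counts), " position barcode(s) absent from counts, ",
         length(missing_in_pos), " count barcode(s) absent from positions")
  }
  pos <- pos[match(barcodes, pos$barcode), , drop = FALSE]

  sf <- jsonlite::read_json(sff)
  diam <- sf$spot_diameter_fullres %||% sf$spot_diameter_px
  if (is.null(diam)) stop("no spot diameter key in ", sff)

  spots <- spot_table(pos$barcode, pos$in_tissue, pos$array_row, pos$array_col,
                      pos$px_row, pos$px_col, as.numeric(diam))
  expr <- expr_matrix(Matrix::t(counts), gene_ids, gene_names, stage = "raw")
  rownames(expr$values) <- barcodes

  channels <- if (is.null(image_path)) list() else {
    load_image_channels(image_path, channel_names)
  }
  if (length(channels)) {
    h <- nrow(channels[[1]]$pixels); w <- ncol(channels[[1]]$pixels)
    bad <- spots$px_row < 0 | spots$px_row > h - 1 |
      spots$px_col < 0 | spots$px_col > w - 1
    if (any(bad & spots$in_tissue)) {
      stop("in-tissue spot centroid(s) outside image bounds: ",
           paste(spots$barcode[bad & spots$in_tissue], collapse = ", "))
    }
  }
  list(spots = spots, expr = expr, channels = channels)
}

find_input_file <- function(path, candidates) {
  if (!dir.exists(path)) stop("input directory not found: ", path)
  for (f in candidates) {
    full <- file.path(path, f)
    if (file.exists(full)) return(full)
  }
  stop("missing input file in ", path, ": expected one of ",
       paste(candidates, collapse = ", "))
}

# Both tissue-positions dialects: the headered spaceranger >= 2.0 CSV and the
# legacy headerless 6-column list. Columns are barcode, in_tissue flag, array
# row/col, pixel row/col (full-resolution).
read_tissue_positions <- function(file) {
  first <- readLines(file, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- read.csv(file, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("tissue positions file must have 6 columns: ", file)
  names(df)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                      "px_row", "px_col")
  df$in_tissue <- as.integer(df$in_tissue) == 1L
  df
}

load_image_channels <- function(image_path, channel_names = NULL) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  pages <- tiff::readTIFF(image_path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  channels <- list()
  for (pg in pages) {
    if (length(dim(pg)) == 3L) {
      nb <- dim(pg)[3]
      # RGB(A) page: split colour bands into separate channels
      band_names <- if (nb >= 3) c("R", "G", "B", "A")[seq_len(nb)] else
        paste0("B", seq_len(nb))
      for (b in seq_len(min(nb, 3L))) {
        channels[[length(channels) + 1L]] <- channel_image(pg[, , b], band_names[b])
      }
    } else {
      channels[[length(channels) + 1L]] <-
        channel_image(pg, paste0("CH", length(channels) + 1L))
    }
  }
  if (!is.null(channel_names)) {
    if (length(channel_names) != length(channels)) {
      stop("channel_names has length ", length(channel_names),
           " but image has ", length(channels), " channel(s)")
    }
    for (i in seq_along(channels)) channels[[i]]$channel_name <- channel_names[i]
  }
  channels
}

#' Write domain labels to CSV
#'
#' @param labels a `domain_labels` object (see [cluster_domains()]).
#' @param spots the matching [spot_table] (row order must correspond).
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
write_labels <- function(labels, spots, file) {
  df <- data.frame(barcode = spots$barcode,
                   raw_domain = labels$raw,
                   refined_domain = labels$refined %||% labels$raw)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
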