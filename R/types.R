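#' Spot table
#'
#' Per-spot metadata for one tissue section: barcode, in-tissue flag, array
#' (lattice) indices and full-resolution pixel coordinates of the spot
#' centroid. Pixel coordinates are 0-based and in row/col order (row = y).
#' The spot diameter in full-resolution pixels is carried as an attribute
#' because it is a single scalar shared by all spots.
#'
#' @param barcode character vector of unique spot barcodes.
#' @param in_tissue logical vector.
#' @param array_row,array_col integer lattice indices.
#' @param px_row,px_col numeric pixel coordinates of centroids (0-based).
#' @param spot_diameter_px positive scalar, spot diameter in pixels.
#' @return A `data.frame` of class `spot_table` with attribute
#'   `spot_diameter_px`.
#' @export
spot_table <- function(barcode, in_tissue, array_row, array_col,
                       px_row, px_col, spot_diameter_px) {
  if (anyDuplicated(barcode)) stop("spot barcodes must be unique")
  if (!is.numeric(spot_diameter_px) || length(spot_diameter_px) != 1L ||
      !is.finite(spot_diameter_px) || spot_diameter_px <= 0) {
    stop("spot_diameter_px must be a single positive number")
  }
  df <- data.frame(
    barcode = as.character(barcode),
    in_tissue = as.logical(in_tissue),
    array_row = as.integer(array_row),
    array_col = as.integer(array_col),
    px_row = as.numeric(px_row),
    px_col = as.numeric(px_col),
    stringsAsFactors = FALSE
  )
  attr(df, "spot_diameter_px") <- as.numeric(spot_diameter_px)
  class(df) <- c("spot_table", "data.frame")
  df
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("<spot_table> %d spots (%d in tissue), spot diameter %.2f px\n",
              nrow(x), sum(x$in_tissue), attr(x, "spot_diameter_px")))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

spot_diameter <- function(spots) attr(spots, "spot_diameter_px")

#' Expression matrix
#'
#' A spots x genes matrix of raw counts or their normalized / scaled
#' derivative, with gene identifiers and a processing-stage marker.
#'
#' @param values numeric or sparse `Matrix` (spots in rows, genes in columns).
#'   Row names are spot barcodes.
#' @param gene_ids,gene_names character vectors, one entry per column.
#' @param stage one of `"raw"`, `"normalized"`, `"scaled"`, `"hvg"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_ids, gene_names = gene_ids,
                        stage = c("raw", "normalized", "scaled", "hvg")) {
  stage <- match.arg(stage)
  if (ncol(values) != length(gene_ids) || length(gene_ids) != length(gene_names)) {
    stop("gene_ids/gene_names must match the number of columns of `values`")
  }
  if (stage == "raw" && min(values) < 0) stop("raw counts must be non-negative")
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         gene_names = as.character(gene_names), stage = stage),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d spots x %d genes, stage = %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# subset genes (columns), keeping metadata in step
subset_genes <- function(expr, j, stage = expr$stage) {
  expr_matrix(expr$values[, j, drop = FALSE],
              gene_ids = expr$gene_ids[j],
              gene_names = expr$gene_names[j],
              stage = stage)
}

subset_spots_expr <- function(expr, i) {
  out <- expr
  out$values <- expr$values[i, , drop = FALSE]
  out
}

#' Single-channel image
#'
#' An H x W matrix of non-negative pixel intensities plus the channel name
#' (e.g. `"DAPI"`, a protein stain, or `"R"`/`"G"`/`"B"` for histology).
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param channel_name single string.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel_name) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (any(!is.finite(pixels))) stop("channel '", channel_name,
                                    "' contains non-finite pixel values")
  structure(list(pixels = pixels, channel_name = as.character(channel_name)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> '%s' %d x %d, range [%.3g, %.3g]\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}
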