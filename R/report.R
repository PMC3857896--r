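#' Selection frequency of genes across DEG sets
#'
#' Counts, for every gene, how many of the supplied DEG sets contain it —
#' e.g. the B bootstrap selections plus the full-data selection produced by
#' [external_b632plus_curve()] (201 sets under the default protocol of 200
#' bootstrap sets). Ordering is by descending count, ties toward the lower
#' gene index.
#'
#' @param deg_sets non-empty list of integer vectors of gene indices
#'   (duplicates within a set are counted once).
#' @param n_genes optional total number of genes; when given, zero-count
#'   genes are included in the table.
#' @return An object of class \code{frequency_table}: data.frame with
#'   columns \code{gene} and \code{count}, attribute \code{n_sets}.
#' @examples
#' deg_frequency(list(c(1, 2), c(2, 3), 2))
#' @export
deg_frequency <- function(deg_sets, n_genes = NULL) {
  if (!is.list(deg_sets) || length(deg_sets) == 0L)
    kmg_stop("bad_input", "deg_sets must be a non-empty list")
  flat <- unlist(lapply(deg_sets, unique), use.names = FALSE)
  n_genes <- n_genes %||% max(flat)
  counts <- tabulate(flat, nbins = n_genes)
  ord <- order(-counts, seq_len(n_genes))
  out <- data.frame(gene = ord, count = as.integer(counts[ord]))
  attr(out, "n_sets") <- length(deg_sets)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Heatmap of top-ranked genes
#'
#' Draws genes (rows, in the supplied order — typically descending selection
#' frequency) against samples (columns) with per-gene z-scored expression on
#' a diverging color key and a top annotation bar marking the class of each
#' sample. The display matrix is echoed to a sidecar CSV next to the image.
#' The per-gene normalization is display-only and never feeds back into
#' scoring.
#'
#' @param ds an [expression_dataset].
#' @param genes ordered gene indices to display (e.g. the top 50 by
#'   frequency).
#' @param out output image path (PNG).
#' @return Invisibly, a list with \code{image} and \code{sidecar} paths.
#' @export
render_heatmap <- function(ds, genes, out) {
  if (any(genes < 1L | genes > ncol(ds$values)))
    kmg_stop("bad_input", "gene indices outside the dataset")
  disp <- t(scale(ds$values[, genes, drop = FALSE]))
  rownames(disp) <- ds$gene_ids[genes]
  colnames(disp) <- ds$sample_ids
  ann <- data.frame(class = factor(ifelse(ds$labels == 1L, "positive", "negative")),
                    row.names = ds$sample_ids)
  sidecar <- paste0(sub("\\.png$", "", out), "_matrix.csv")
  utils::write.csv(disp, sidecar, row.names = TRUE)
  pheatmap::pheatmap(
    disp,
    cluster_rows = FALSE, cluster_cols = FALSE,
    annotation_col = ann,
    color = grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101),
    show_colnames = ncol(disp) <= 40,
    filename = out, silent = TRUE)
  invisible(list(image = out, sidecar = sidecar))
}
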