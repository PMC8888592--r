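#' Paired mRNA + ADT single-cell dataset
#'
#' Container for a CITE-seq experiment: a sparse gene-by-cell count matrix, a
#' dense antibody-by-cell ADT count matrix over the *same* cell barcodes, a
#' feature table describing both modalities, and per-cell metadata (fraction
#' of origin, species call, QC flag, cluster label, scores).
#'
#' @param rna sparse (or dense) integer count matrix, genes x cells. Row names
#'   are feature ids, column names are cell barcodes.
#' @param adt numeric count matrix, antibodies x cells, column names identical
#'   to `colnames(rna)` in the same order.
#' @param features data.frame with columns `id`, `name`, `species`
#'   (`"human"`/`"mouse"`), `type` (`"gene"`/`"antibody"`), one row per mRNA
#'   feature followed by one row per antibody.
#' @param meta per-cell data.frame; must contain a `barcode` column matching
#'   the matrix columns, typically also `fraction`.
#'
#' @return An object of class `multimodal_dataset`: a list with elements
#'   `rna`, `adt`, `features`, `meta`, `barcodes`.
#' @export
multimodal_dataset <- function(rna, adt, features, meta) {
  if (is.null(colnames(rna)) || is.null(colnames(adt)))
    stop("rna and adt must carry cell barcodes as column names")
  if (!identical(colnames(rna), colnames(adt)))
    stop("rna and adt must share an identical barcode order")
  if (anyDuplicated(colnames(rna)))
    stop("duplicate cell barcodes")
  if (anyDuplicated(features$id))
    stop("duplicate feature ids")
  if (!"barcode" %in% names(meta))
    stop("meta must contain a 'barcode' column")
  if (!identical(as.character(meta$barcode), colnames(rna)))
    stop("meta rows must align with the barcode order of the matrices")
  rna <- methods::as(methods::as(rna, "CsparseMatrix"), "generalMatrix")
  adt <- as.matrix(adt)
  structure(
    list(rna = rna, adt = adt, features = features, meta = meta,
         barcodes = colnames(rna)),
    class = "multimodal_dataset"
  )
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("multimodal_dataset:", ncol(x$rna), "cells\n")
  cat("  mRNA:", nrow(x$rna), "genes (sparse,",
      format(Matrix::nnzero(x$rna), big.mark = ","), "non-zero)\n")
  cat("  ADT :", nrow(x$adt), "antibodies\n")
  if ("fraction" %in% names(x$meta)) {
    tab <- table(x$meta$fraction)
    cat("  fractions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a multimodal dataset by cells
#'
#' @param x a `multimodal_dataset`
#' @param cells logical mask, integer index or character barcodes
#' @return the subsetted `multimodal_dataset`
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "multimodal_dataset"))
  if (is.character(cells)) cells <- match(cells, x$barcodes)
  if (is.logical(cells)) cells <- which(cells)
  if (anyNA(cells)) stop("unknown barcodes in cell subset")
  multimodal_dataset(x$rna[, cells, drop = FALSE],
                     x$adt[, cells, drop = FALSE],
                     x$features,
                     x$meta[cells, , drop = FALSE])
}

#' Per-cell UMI totals split by feature species
#'
#' Sums mRNA counts over human-annotated and mouse-annotated genes; used by
#' [assign_species()].
#'
#' @param dataset a `multimodal_dataset`
#' @return data.frame with `barcode`, `human_umis`, `mouse_umis`
#' @export
species_umi_totals <- function(dataset) {
  genes <- dataset$features[dataset$features$type == "gene", ]
  hgenes <- genes$id[genes$species == "human"]
  mgenes <- genes$id[genes$species == "mouse"]
  data.frame(
    barcode = dataset$barcodes,
    human_umis = Matrix::colSums(dataset$rna[hgenes, , drop = FALSE]),
    mouse_umis = if (length(mgenes))
      Matrix::colSums(dataset$rna[mgenes, , drop = FALSE])
    else rep(0, length(dataset$barcodes)),
    row.names = NULL
  )
}
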