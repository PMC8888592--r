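#' Read a 10x CellRanger-style sparse matrix directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' optionally gzipped. MatrixMarket indices are 1-based on disk and the
#' counts are preserved exactly. The features file may carry 1-4 columns
#' (id, name, type, species); missing columns are filled in, and a feature
#' id prefixed `mm10-` (or `mm10___`) is annotated as mouse.
#'
#' @param directory path containing the three files
#' @return list with `matrix` (sparse dgCMatrix, features x cells, dimnames
#'   set), `features` (data.frame id/name/species/type) and `barcodes`
#' @export
read_10x_mtx <- function(directory) {
  find <- function(bases) {
    for (b in bases) for (ext in c("", ".gz")) {
      p <- file.path(directory, paste0(b, ext))
      if (file.exists(p)) return(p)
    }
    stop("missing ", bases[1], " in ", directory)
  }
  mtx <- find("matrix.mtx")
  fpath <- find(c("features.tsv", "genes.tsv"))
  bpath <- find("barcodes.tsv")
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feats <- utils::read.delim(fpath, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(bpath)
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m))
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but features/barcodes have ", nrow(feats), "/", length(barcodes),
         " entries")
  features <- data.frame(
    id = feats[[1]],
    name = if (ncol(feats) >= 2) feats[[2]] else feats[[1]],
    species = if (ncol(feats) >= 4) feats[[4]]
              else ifelse(grepl("^mm10[-_]", feats[[1]]), "mouse", "human"),
    type = if (ncol(feats) >= 3)
             ifelse(feats[[3]] %in% c("Antibody Capture", "antibody"),
                    "antibody", "gene")
           else "gene",
    stringsAsFactors = FALSE)
  if (anyDuplicated(features$id)) stop("duplicate feature ids")
  dimnames(m) <- list(features$id, barcodes)
  list(matrix = m, features = features, barcodes = barcodes)
}

#' Read an ADT count CSV and align it to a barcode order
#'
#' The file holds one row per antibody (first column = antibody name) and
#' one column per cell barcode. Columns are re-ordered to match `barcodes`;
#' a barcode absent from the file is an error naming the missing cells.
#'
#' @param path CSV path
#' @param barcodes required barcode order (e.g. from [read_10x_mtx()])
#' @return numeric matrix, antibodies x cells, columns in `barcodes` order
#' @export
read_adt_csv <- function(path, barcodes) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ab <- tab[[1]]
  if (anyDuplicated(ab)) stop("duplicate antibody names in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ab
  missing <- setdiff(barcodes, colnames(m))
  if (length(missing))
    stop("ADT file is missing barcode(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  m[, barcodes, drop = FALSE]
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory fixture directory
#' @return list with `dataset` (a [multimodal_dataset()]) and `truth`
#' @export
read_fixture <- function(directory) {
  tenx <- read_10x_mtx(directory)
  adt <- read_adt_csv(file.path(directory, "adt.csv"), tenx$barcodes)
  truth <- utils::read.delim(file.path(directory, "truth.tsv"),
                             stringsAsFactors = FALSE)
  features <- rbind(
    tenx$features,
    data.frame(id = paste0("ADT-", rownames(adt)), name = rownames(adt),
               species = "human", type = "antibody",
               stringsAsFactors = FALSE))
  meta <- truth[, intersect(c("barcode", "fraction", "cluster"), names(truth))]
  dataset <- multimodal_dataset(tenx$matrix, adt, features, meta)
  list(dataset = dataset, truth = truth)
}
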