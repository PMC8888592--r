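#' Assign each cell a species label from mixed-reference UMI totals
#'
#' Cells from libraries mapped against a joint human + mouse reference are
#' labelled by the fraction of their UMIs on human genes:
#' `human` when `human/(human+mouse) >= high_thr`, `mouse` when
#' `<= low_thr`, and `doublet` in between. Cells with zero total UMIs cannot
#' be classified: they are labelled `NA` and a warning is raised.
#'
#' @param human_umis,mouse_umis non-negative per-cell UMI totals
#' @param high_thr,low_thr thresholds with `0 <= low_thr < high_thr <= 1`
#' @return character vector of labels (`human`/`mouse`/`doublet`/`NA`)
#' @export
assign_species <- function(human_umis, mouse_umis,
                           high_thr = 0.9, low_thr = 0.1) {
  stopifnot(length(human_umis) == length(mouse_umis))
  if (!(low_thr >= 0 && low_thr < high_thr && high_thr <= 1))
    stop("thresholds must satisfy 0 <= low_thr < high_thr <= 1")
  if (any(human_umis < 0) || any(mouse_umis < 0))
    stop("UMI totals must be non-negative")
  total <- human_umis + mouse_umis
  frac <- human_umis / total
  lab <- ifelse(frac >= high_thr, "human",
                ifelse(frac <= low_thr, "mouse", "doublet"))
  if (any(total == 0)) {
    warning(sum(total == 0), " cell(s) with zero total UMIs excluded from ",
            "species assignment")
    lab[total == 0] <- NA_character_
  }
  lab
}

#' Empirical doublet rate per fraction
#'
#' The proportion of cells labelled `doublet` among all classified cells of
#' each fraction: the operational doublet-rate estimate available when
#' human and mouse cells are co-loaded.
#'
#' @param species per-cell labels from [assign_species()]
#' @param fraction per-cell fraction-of-origin labels (same length)
#' @return named numeric vector of per-fraction rates in `[0, 1]`; a
#'   fraction with no classified cell is reported as `NA`
#' @export
estimate_doublet_rate <- function(species, fraction) {
  stopifnot(length(species) == length(fraction))
  keep <- !is.na(species)
  vapply(split(species[keep], fraction[keep]), function(s) {
    if (length(s) == 0) return(NA_real_)
    mean(s == "doublet")
  }, numeric(1))
}

#' Mitochondrial-content filter
#'
#' Flags cells whose share of UMIs on mitochondrial genes exceeds
#' `max_fraction`. The inequality is strict: a cell at exactly the threshold
#' passes, a cell above it is removed (more than 25% mitochondrial reads by
#' default).
#'
#' @param counts gene x cell count matrix (sparse or dense) with gene row
#'   names
#' @param mito_gene_set character vector of mitochondrial gene ids (subset of
#'   `rownames(counts)`)
#' @param max_fraction maximum tolerated mitochondrial share (default 0.25)
#' @return list with `pass` (logical per cell) and `mito_fraction` (numeric
#'   per cell, 0 for zero-total cells)
#' @export
mito_filter <- function(counts, mito_gene_set, max_fraction = 0.25) {
  if (length(mito_gene_set) == 0) {
    warning("empty mitochondrial gene set: all cells pass")
    return(list(pass = rep(TRUE, ncol(counts)),
                mito_fraction = rep(0, ncol(counts))))
  }
  if (!all(mito_gene_set %in% rownames(counts)))
    stop("mito_gene_set contains genes absent from the matrix")
  total <- Matrix::colSums(counts)
  mito <- Matrix::colSums(counts[mito_gene_set, , drop = FALSE])
  frac <- ifelse(total == 0, 0, mito / total)
  list(pass = frac <= max_fraction, mito_fraction = as.numeric(frac))
}

#' Full QC report for a multimodal dataset
#'
#' Runs species assignment, per-fraction doublet-rate estimation and the
#' mitochondrial filter, and combines them into one per-cell table. A cell
#' passes QC iff it is labelled human and its mitochondrial content is at or
#' below the threshold. Mouse cells never pass but are deliberately retained
#' downstream: they feed the ADT background model.
#'
#' @param dataset a [multimodal_dataset()]
#' @param mito_genes mitochondrial gene ids; default: human genes whose name
#'   starts with `MT-`
#' @param mito_max mitochondrial threshold (default 0.25)
#' @param species_high,species_low species-assignment thresholds
#' @return object of class `qc_report`: list with `cells` (per-cell
#'   data.frame: barcode, fraction, species, mito_fraction, pass),
#'   `doublet_rate` (per fraction) and `summary` (per-fraction counts)
#' @export
qc_report <- function(dataset, mito_genes = NULL, mito_max = 0.25,
                      species_high = 0.9, species_low = 0.1) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  umis <- species_umi_totals(dataset)
  species <- assign_species(umis$human_umis, umis$mouse_umis,
                            species_high, species_low)
  if (is.null(mito_genes)) {
    genes <- dataset$features[dataset$features$type == "gene", ]
    mito_genes <- genes$id[grepl("^MT-", genes$name)]
  }
  mf <- mito_filter(dataset$rna, mito_genes, mito_max)
  fraction <- dataset$meta$fraction
  cells <- data.frame(
    barcode = dataset$barcodes, fraction = fraction, species = species,
    mito_fraction = mf$mito_fraction,
    pass = !is.na(species) & species == "human" & mf$pass,
    stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(split(cells, cells$fraction), function(d)
    data.frame(fraction = d$fraction[1], n = nrow(d),
               n_human = sum(d$species == "human", na.rm = TRUE),
               n_mouse = sum(d$species == "mouse", na.rm = TRUE),
               n_doublet = sum(d$species == "doublet", na.rm = TRUE),
               n_pass = sum(d$pass))))
  rownames(summary) <- NULL
  structure(list(cells = cells,
                 doublet_rate = estimate_doublet_rate(species, fraction),
                 summary = summary),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report over", nrow(x$cells), "cells\n")
  print(x$summary, row.names = FALSE)
  cat("estimated doublet rate:",
      paste(sprintf("%s=%.4f", names(x$doublet_rate), x$doublet_rate),
            collapse = ", "), "\n")
  invisible(x)
}
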