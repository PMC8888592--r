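#' Centered log-ratio transform of ADT counts, one marker at a time
#'
#' For each antibody the raw count vector `x` over all cells (human cells
#' and mouse spike-ins of one fraction together) is mapped to
#' `y = log(1 + x / g)` with `g = exp(sum(log1p(x[x > 0])) / n_cells)`: the
#' geometric-mean denominator accumulates only the non-zero entries but
#' divides by the total cell count. An all-zero marker maps to an all-zero
#' row (`g = 1`).
#'
#' @param adt_counts non-negative count matrix, antibodies x cells
#' @return object of class `clr_matrix`: list with `values` (same shape),
#'   `transform` tag and `log_geo_mean` (per-antibody log denominator)
#' @export
clr_transform <- function(adt_counts) {
  x <- as.matrix(adt_counts)
  if (any(x < 0)) stop("ADT counts must be non-negative")
  n <- ncol(x)
  lx <- log1p(x)
  log_g <- rowSums(lx) / n       # log1p(0) = 0, so zeros drop out of the sum
  vals <- log1p(x / exp(log_g))
  dimnames(vals) <- dimnames(x)
  structure(list(values = vals, transform = "clr", log_geo_mean = log_g),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat(sprintf("clr_matrix [%s]: %d ADTs x %d cells\n",
              x$transform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Fit the spike-in background model
#'
#' Per antibody, the mean and sample standard deviation (n - 1 denominator)
#' of the CLR-transformed counts over the mouse spike-in cells; the
#' background cutoff is one standard deviation above that mean.
#'
#' @param clr a [clr_transform()] result over human + spike-in cells of one
#'   fraction
#' @param spike_in_mask logical mask (or barcodes) marking the spike-in cells
#' @param n_sd number of standard deviations above the spike-in mean
#'   defining the cutoff (default 1)
#' @return object of class `adt_background`: data.frame with `adt`, `mean`,
#'   `sd`, `cutoff`, `n`
#' @export
fit_background <- function(clr, spike_in_mask, n_sd = 1) {
  stopifnot(inherits(clr, "clr_matrix"))
  if (is.character(spike_in_mask))
    spike_in_mask <- colnames(clr$values) %in% spike_in_mask
  v <- clr$values[, spike_in_mask, drop = FALSE]
  if (ncol(v) < 2)
    stop("at least 2 spike-in cells are required (SD undefined otherwise)")
  m <- rowMeans(v)
  s <- apply(v, 1, stats::sd)
  out <- data.frame(adt = rownames(clr$values), mean = m, sd = s,
                    cutoff = m + n_sd * s, n = ncol(v),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("adt_background", "data.frame")
  out
}

#' Subtract the spike-in background cutoff from human cells
#'
#' `corrected = max(0, clr - cutoff)` per antibody; values below the cutoff
#' are treated as indistinguishable from non-specific staining. Spike-in
#' cells are dropped from the output.
#'
#' @param clr a `clr_matrix` over human + spike-in cells
#' @param model an [fit_background()] model fitted on the same antibodies
#' @param human_mask logical mask (or barcodes) of the human cells to keep
#' @return a `clr_matrix` with `transform = "corrected"` over the human cells
#' @export
subtract_background <- function(clr, model, human_mask) {
  stopifnot(inherits(clr, "clr_matrix"), inherits(model, "adt_background"))
  if (!identical(rownames(clr$values), model$adt))
    stop("ADT mismatch between CLR matrix and background model")
  if (is.character(human_mask))
    human_mask <- colnames(clr$values) %in% human_mask
  v <- clr$values[, human_mask, drop = FALSE]
  corrected <- pmax(v - model$cutoff, 0)
  structure(list(values = corrected, transform = "corrected",
                 log_geo_mean = clr$log_geo_mean),
            class = "clr_matrix")
}

#' Cap values above a quantile (display only)
#'
#' Values above the `q`-quantile (type-7) are clamped to that quantile —
#' the `q99` outlier-capping convention used for feature plots. Capping is
#' never applied before gating or enrichment computations.
#'
#' @param values numeric vector or matrix (capped per row when a matrix)
#' @param q quantile in `(0, 1]`; `q = 1` is the identity
#' @return capped values, same shape
#' @export
cap_outliers <- function(values, q = 0.99) {
  stopifnot(q > 0, q <= 1)
  if (is.matrix(values)) {
    out <- t(apply(values, 1, function(r) pmin(r, stats::quantile(r, q))))
    dimnames(out) <- dimnames(values)
    return(out)
  }
  pmin(values, stats::quantile(values, q))
}

#' Per-fraction ADT processing: CLR, background fit, subtraction
#'
#' Runs the full ADT stage the way the experiment dictates: each fraction is
#' CLR-transformed jointly over its human cells and its own mouse spike-ins,
#' the background model is fitted on those spike-ins alone (never pooled
#' across fractions), and the cutoff is subtracted from the human cells.
#'
#' @param dataset a [multimodal_dataset()]
#' @param species per-cell species labels (from [qc_report()])
#' @param human_keep optional logical mask of human cells to retain in the
#'   output (e.g. QC-passing cells); defaults to all human cells
#' @param n_sd cutoff width in spike-in SDs (default 1)
#' @return list with `corrected` (antibodies x human cells matrix, all
#'   fractions re-combined), `background` (per-fraction `adt_background`),
#'   `clr` (per-fraction raw `clr_matrix`)
#' @export
process_adt <- function(dataset, species, human_keep = NULL, n_sd = 1) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  if (is.null(human_keep)) human_keep <- !is.na(species) & species == "human"
  fraction <- dataset$meta$fraction
  bg <- list(); clrs <- list(); corrected <- list()
  for (frac in unique(fraction)) {
    in_frac <- fraction == frac
    spike <- in_frac & !is.na(species) & species == "mouse"
    keep <- in_frac & human_keep
    use <- spike | keep
    clr <- clr_transform(dataset$adt[, use, drop = FALSE])
    model <- fit_background(clr, spike[use], n_sd = n_sd)
    clrs[[frac]] <- clr
    bg[[frac]] <- model
    corrected[[frac]] <- subtract_background(clr, model, keep[use])$values
  }
  corr <- do.call(cbind, corrected)
  # restore the dataset's barcode order among retained human cells
  corr <- corr[, dataset$barcodes[human_keep], drop = FALSE]
  list(corrected = corr, background = bg, clr = clrs)
}
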