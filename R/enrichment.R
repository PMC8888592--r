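#' Progressive enrichment curve for one marker
#'
#' For each selection level `f`, the `ceiling(f * N)` cells with the highest
#' marker value are selected (stable tie-break by ascending barcode) and the
#' proportion of the target cluster among them is reported. At level 1 the
#' proportion equals the global cluster proportion exactly.
#'
#' @param marker_values named numeric vector (names = barcodes) of the
#'   background-corrected ADT values for one marker
#' @param cluster_labels per-cell cluster labels, aligned with
#'   `marker_values`
#' @param target_cluster label of the cluster of interest
#' @param levels selection levels in `(0, 1]`, reported in the given order
#' @return object of class `enrichment_curve`: data.frame with `level`,
#'   `proportion`, `n_selected`; attribute `marker`
#' @export
enrichment_curve <- function(marker_values, cluster_labels, target_cluster,
                             levels = c(1, 0.5, 0.25, 0.10, 0.05),
                             marker = "marker") {
  stopifnot(length(marker_values) == length(cluster_labels),
            all(levels > 0), all(levels <= 1))
  if (!target_cluster %in% cluster_labels)
    stop("target cluster '", target_cluster, "' absent from the labels")
  bc <- names(marker_values)
  if (is.null(bc)) bc <- sprintf("cell%07d", seq_along(marker_values))
  ord <- order(-marker_values, bc)
  n <- length(marker_values)
  rows <- lapply(levels, function(f) {
    k <- ceiling(f * n)
    sel <- ord[seq_len(k)]
    data.frame(level = f,
               proportion = mean(cluster_labels[sel] == target_cluster),
               n_selected = k)
  })
  out <- do.call(rbind, rows)
  attr(out, "marker") <- marker
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

#' Target-cluster proportion at one selection level, per marker
#'
#' Evaluates [enrichment_curve()] at a single level (default: top 5%) for
#' every marker of a corrected ADT matrix and tabulates the resulting
#' target-cluster proportions in decreasing order.
#'
#' @param corrected_adt markers x cells matrix of background-corrected ADT
#'   values (barcodes as column names)
#' @param cluster_labels,target_cluster as in [enrichment_curve()]
#' @param level single selection level in `(0, 1]`
#' @return data.frame with `marker`, `proportion`, `n_selected`, sorted by
#'   decreasing proportion
#' @export
marker_comparison <- function(corrected_adt, cluster_labels, target_cluster,
                              level = 0.05) {
  rows <- lapply(rownames(corrected_adt), function(m) {
    cv <- enrichment_curve(corrected_adt[m, ], cluster_labels, target_cluster,
                           levels = level, marker = m)
    data.frame(marker = m, proportion = cv$proportion,
               n_selected = cv$n_selected)
  })
  out <- do.call(rbind, rows)
  out[order(-out$proportion, out$marker), , drop = FALSE]
}

#' Cluster-composition dynamics between two fractions
#'
#' Per-cluster proportions in fraction A and fraction B over their shared
#' label universe, with the fold change B/A. A cluster absent from A has an
#' undefined fold change, reported as `NA`.
#'
#' @param labels_a,labels_b per-cell cluster labels of the two fractions
#' @return object of class `cluster_dynamics`: data.frame with `cluster`,
#'   `prop_a`, `prop_b`, `fold_change`
#' @export
cluster_dynamics <- function(labels_a, labels_b) {
  if (length(labels_a) == 0 || length(labels_b) == 0)
    stop("both fractions must contain cells")
  universe <- sort(unique(c(labels_a, labels_b)))
  pa <- as.numeric(table(factor(labels_a, universe)) / length(labels_a))
  pb <- as.numeric(table(factor(labels_b, universe)) / length(labels_b))
  out <- data.frame(cluster = universe, prop_a = pa, prop_b = pb,
                    fold_change = ifelse(pa == 0, NA_real_, pb / pa),
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_dynamics", "data.frame")
  out
}

#' Cell-cycle phase composition per fraction (and optionally per cluster)
#'
#' @param phases factor of phase calls (`G1`/`S`/`G2M`), e.g.
#'   `cell_cycle_phase(...)$phase`
#' @param fractions per-cell fraction labels
#' @param clusters optional per-cell cluster labels for a per-cluster
#'   breakdown
#' @return data.frame with `fraction` (and `cluster`), `G1`, `S`, `G2M`
#'   proportions summing to 1 per row
#' @export
phase_composition <- function(phases, fractions, clusters = NULL) {
  phases <- factor(phases, levels = c("G1", "S", "G2M"))
  stopifnot(length(phases) == length(fractions))
  key <- if (is.null(clusters)) list(fraction = fractions)
         else list(fraction = fractions, cluster = clusters)
  tab <- stats::aggregate(seq_along(phases), key, function(i) i,
                          simplify = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(r) {
    idx <- tab$x[[r]]
    props <- as.numeric(table(phases[idx]) / length(idx))
    cbind(tab[r, setdiff(names(tab), "x"), drop = FALSE],
          data.frame(G1 = props[1], S = props[2], G2M = props[3]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
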