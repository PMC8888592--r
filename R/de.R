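#' Differential expression between a cell set and the remaining background
#'
#' Per-gene two-sided Wilcoxon rank-sum test (normal approximation,
#' tie-corrected) on log-normalized expression, Benjamini-Hochberg adjusted
#' across the tested genes. Genes expressed in fewer than `min_pct` of the
#' cells of both groups are not tested. The fold change is computed on the
#' de-logged scale: `lfc = ln((mean(expm1(x_grp)) + 1) /
#' (mean(expm1(x_bg)) + 1))`.
#'
#' @param expr normalized expression (genes x cells), e.g. [log_normalize()]
#' @param group_mask logical mask (or barcodes) of the cell set of interest;
#'   the background is every other cell
#' @param alpha BH-adjusted significance level (default 0.05)
#' @param lfc_min minimum absolute log fold change for the significance flag
#'   (default 0.25)
#' @param min_pct minimum expressing-cell fraction in at least one group
#'   (default 0.10)
#' @return object of class `deg_table`: data.frame with `gene`, `lfc`,
#'   `p`, `q`, `pct_group`, `pct_background`, `significant`, ordered by
#'   decreasing `lfc`; untested genes are absent
#' @export
differential_expression <- function(expr, group_mask, alpha = 0.05,
                                    lfc_min = 0.25, min_pct = 0.10) {
  if (is.character(group_mask)) group_mask <- colnames(expr) %in% group_mask
  stopifnot(length(group_mask) == ncol(expr))
  if (all(group_mask)) stop("group must not contain every cell")
  if (!any(group_mask)) stop("group is empty")
  grp <- which(group_mask); bg <- which(!group_mask)
  x <- as.matrix(expr)
  pct_g <- rowMeans(x[, grp, drop = FALSE] > 0)
  pct_b <- rowMeans(x[, bg, drop = FALSE] > 0)
  tested <- which(pmax(pct_g, pct_b) >= min_pct)
  if (length(tested) == 0)
    return(structure(data.frame(gene = character(0), lfc = numeric(0),
                                p = numeric(0), q = numeric(0),
                                pct_group = numeric(0),
                                pct_background = numeric(0),
                                significant = logical(0)),
                     class = c("deg_table", "data.frame")))
  mean_g <- rowMeans(expm1(x[tested, grp, drop = FALSE]))
  mean_b <- rowMeans(expm1(x[tested, bg, drop = FALSE]))
  lfc <- log((mean_g + 1) / (mean_b + 1))
  p <- vapply(tested, function(i) {
    xi <- x[i, ]
    if (all(xi[grp] == xi[grp][1]) && all(xi == xi[1])) return(1)
    stats::wilcox.test(xi[grp], xi[bg], exact = FALSE)$p.value
  }, numeric(1))
  p[is.na(p)] <- 1   # zero-variance genes that slipped the prefilter
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(x)[tested], lfc = lfc, p = p, q = q,
                    pct_group = pct_g[tested], pct_background = pct_b[tested],
                    significant = q < alpha & abs(lfc) > lfc_min,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$lfc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Significant gene set of a DEG table
#'
#' @param deg a `deg_table`
#' @param direction `"up"` (positive lfc only), `"down"`, or `"both"`
#' @return character vector of gene ids
#' @export
deg_genes <- function(deg, direction = c("up", "both", "down")) {
  direction <- match.arg(direction)
  keep <- deg$significant
  if (direction == "up") keep <- keep & deg$lfc > 0
  if (direction == "down") keep <- keep & deg$lfc < 0
  deg$gene[keep]
}

#' Directional overlap of DEG sets against a reference signature
#'
#' For each non-reference set A, the shared percentage is
#' `100 * |A intersect R| / |A|` — each signature's own set size is the
#' denominator, so the number answers "how much of this signature's DEG set
#' is contained in the reference signature's set". Pairwise Venn counts and
#' the full intersection are also reported.
#'
#' @param sets named list (>= 2) of character gene sets
#' @param reference name of the reference set
#' @return object of class `overlap_report`: list with `shared_pct` (named,
#'   `NA` for an empty set), `pairwise` (data.frame with sizes and
#'   intersections), `n_common` and `common`
#' @export
overlap_report <- function(sets, reference) {
  stopifnot(length(sets) >= 2, reference %in% names(sets))
  ref <- sets[[reference]]
  others <- setdiff(names(sets), reference)
  shared_pct <- vapply(others, function(nm) {
    a <- sets[[nm]]
    if (length(a) == 0) return(NA_real_)
    100 * length(intersect(a, ref)) / length(a)
  }, numeric(1))
  pairs <- utils::combn(names(sets), 2)
  pairwise <- data.frame(
    a = pairs[1, ], b = pairs[2, ],
    n_a = lengths(sets)[pairs[1, ]], n_b = lengths(sets)[pairs[2, ]],
    n_intersect = apply(pairs, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    row.names = NULL)
  common <- Reduce(intersect, sets)
  structure(list(shared_pct = shared_pct, pairwise = pairwise,
                 common = common, n_common = length(common),
                 reference = reference),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report (reference:", x$reference, ")\n")
  for (nm in names(x$shared_pct))
    cat(sprintf("  %s: %.2f%% shared with reference\n", nm, x$shared_pct[nm]))
  cat("  common to all sets:", x$n_common, "genes\n")
  invisible(x)
}

#' Rank of the reference signature's top genes across signatures
#'
#' Within each DEG table, significant genes are ranked by decreasing log
#' fold change. The reference's `top_n` genes are then looked up in every
#' other signature's ranking; a gene outside a signature's significant set
#' is recorded as absent (`NA`), never as rank 0.
#'
#' @param tables named list of `deg_table` objects sharing a gene universe
#' @param reference name of the reference table
#' @param top_n number of reference genes to report (default 25; truncated
#'   with a warning when the reference has fewer significant genes)
#' @return data.frame: `gene` plus one integer rank column per signature
#' @export
rank_table <- function(tables, reference, top_n = 25) {
  stopifnot(reference %in% names(tables))
  ranked <- lapply(tables, function(t) {
    g <- t[t$significant & t$lfc > 0, , drop = FALSE]
    g <- g[order(-g$lfc, g$gene), , drop = FALSE]
    stats::setNames(seq_len(nrow(g)), g$gene)
  })
  ref_rank <- ranked[[reference]]
  if (top_n > length(ref_rank)) {
    warning("reference has only ", length(ref_rank),
            " significant genes; truncating")
    top_n <- length(ref_rank)
  }
  top <- names(ref_rank)[seq_len(top_n)]
  out <- data.frame(gene = top, stringsAsFactors = FALSE)
  for (nm in names(tables))
    out[[nm]] <- unname(ranked[[nm]][top])
  out
}
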