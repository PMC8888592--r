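#' Library-size log-normalization
#'
#' Each cell's counts are scaled to a common total (`scale`, default 10,000)
#' and mapped through `log1p`. A zero-total cell maps to zeros with a
#' warning.
#'
#' @param counts gene x cell count matrix (sparse or dense)
#' @param scale common library-size target
#' @return dense numeric matrix of class `normalized_expression`
#'   (genes x cells) with attribute `scale`
#' @export
log_normalize <- function(counts, scale = 1e4) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- Matrix::colSums(counts)
  if (any(total == 0))
    warning(sum(total == 0), " zero-total cell(s) normalized to all zeros")
  denom <- ifelse(total == 0, 1, total)
  x <- as.matrix(counts)
  out <- log1p(sweep(x, 2, scale / denom, `*`))
  attr(out, "scale") <- scale
  class(out) <- c("normalized_expression", class(out))
  out
}

# Equal-frequency expression bins over genes: rank gene means (ties broken
# by gene order) and cut into nbin bins of near-equal size.
expression_bins <- function(expr, nbin) {
  gene_means <- rowMeans(expr)
  ranks <- rank(gene_means, ties.method = "first")
  as.integer(ceiling(nbin * ranks / length(ranks)))
}

#' Gene-module score with expression-matched controls
#'
#' Tirosh-style scoring: genes are ranked by mean normalized expression and
#' cut into `nbin` equal-frequency bins; for every program gene, `n_ctrl`
#' control genes are drawn (without replacement, seeded) from that gene's
#' bin; the per-cell score is the mean expression of the program genes minus
#' the mean expression of the pooled control draw (duplicates across program
#' genes retained, so the control weighting matches the per-gene sampling).
#'
#' @param expr normalized expression matrix (genes x cells), e.g. from
#'   [log_normalize()]
#' @param program_genes character vector of program gene ids (must all be
#'   present in `rownames(expr)`)
#' @param nbin number of expression bins (default 24)
#' @param n_ctrl controls sampled per program gene (default 100); truncated
#'   to the bin size when a bin is smaller
#' @param seed integer seed controlling the control draw
#' @return object of class `module_score`: list with `score` (named per-cell
#'   numeric), `program`, `controls` (pooled control ids, duplicates kept),
#'   `nbin`, `n_ctrl`, `seed`
#' @export
module_score <- function(expr, program_genes, nbin = 24, n_ctrl = 100,
                         seed = 1L) {
  stopifnot(nbin >= 1, n_ctrl >= 1)
  missing <- setdiff(program_genes, rownames(expr))
  if (length(missing))
    stop("program genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  bins <- expression_bins(expr, nbin)
  prog_idx <- match(program_genes, rownames(expr))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ctrl_idx <- integer(0)
  for (g in prog_idx) {
    members <- which(bins == bins[g])
    k <- min(n_ctrl, length(members))
    ctrl_idx <- c(ctrl_idx, members[sample.int(length(members), k)])
  }
  score <- colMeans(expr[prog_idx, , drop = FALSE]) -
    colMeans(expr[ctrl_idx, , drop = FALSE])
  structure(list(score = score, program = program_genes,
                 controls = rownames(expr)[ctrl_idx],
                 nbin = nbin, n_ctrl = n_ctrl, seed = seed),
            class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("module_score: %d program genes, %d pooled controls, %d cells\n",
              length(x$program), length(x$controls), length(x$score)))
  cat(sprintf("  nbin=%d n_ctrl=%d seed=%d; score range [%.3f, %.3f]\n",
              x$nbin, x$n_ctrl, x$seed, min(x$score), max(x$score)))
  invisible(x)
}

#' Cell-cycle phase from S and G2M module scores
#'
#' A cell is called `S` when its S score exceeds both its G2M score and 0,
#' `G2M` symmetrically, and `G1` otherwise (both scores non-positive, or an
#' exact tie — ties are measure-zero but must resolve deterministically).
#'
#' @param s,g2m `module_score` objects (or bare numeric vectors) over the
#'   same cells
#' @return object of class `cell_cycle_call`: list with `phase` (factor
#'   G1/S/G2M), `s_score`, `g2m_score`
#' @export
cell_cycle_phase <- function(s, g2m) {
  sv <- if (inherits(s, "module_score")) s$score else s
  gv <- if (inherits(g2m, "module_score")) g2m$score else g2m
  stopifnot(length(sv) == length(gv))
  phase <- rep("G1", length(sv))
  phase[sv > gv & sv > 0] <- "S"
  phase[gv > sv & gv > 0] <- "G2M"
  structure(list(phase = factor(phase, levels = c("G1", "S", "G2M")),
                 s_score = sv, g2m_score = gv),
            class = "cell_cycle_call")
}

#' Tirosh cell-cycle gene lists
#'
#' The published S-phase and G2M-phase marker lists shipped with the package
#' as a plain-text fixture, for use on real human gene symbols.
#'
#' @return list with `s_genes` and `g2m_genes` character vectors
#' @export
cell_cycle_genes <- function() {
  path <- system.file("extdata", "cell_cycle_genes.tsv", package = "citesort")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(s_genes = tab$gene[tab$phase == "S"],
       g2m_genes = tab$gene[tab$phase == "G2M"])
}

#' GPI-80 pseudo-marker score and top-fraction selection
#'
#' GPI-80 protein marks engraftable HSCs but has no usable ADT; its identity
#' is approximated by a module score over the top genes enriched in the
#' functionally sorted fraction. The `ceiling(top_fraction * n)` CD34+ cells
#' with the highest score are selected (2.37% by default — the measured size
#' of the GPI-80+ fraction within CD34+ cells), ties broken by ascending
#' barcode.
#'
#' @param expr normalized expression over the cells under consideration
#' @param top_genes character vector of program genes (typically the 30 most
#'   enriched genes of the functionally enriched fraction)
#' @param cd34_mask logical mask of CD34+ cells within `colnames(expr)`
#' @param top_fraction fraction of CD34+ cells to select, in `(0, 1]`
#' @param nbin,n_ctrl,seed passed to [module_score()]
#' @return list with `score` (a `module_score` over all cells), `selected`
#'   (barcodes of selected CD34+ cells) and `n_selected`
#' @export
gpi80_score <- function(expr, top_genes, cd34_mask, top_fraction = 0.0237,
                        nbin = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (!any(cd34_mask)) stop("empty CD34+ mask")
  ms <- module_score(expr, top_genes, nbin = nbin, n_ctrl = n_ctrl, seed = seed)
  bc <- colnames(expr)
  cand <- which(cd34_mask)
  k <- as.integer(ceiling(top_fraction * length(cand)))
  ord <- cand[order(-ms$score[cand], bc[cand])]
  selected <- bc[ord[seq_len(k)]]
  list(score = ms, selected = selected, n_selected = k)
}
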