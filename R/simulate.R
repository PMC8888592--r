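#' Configuration for the synthetic CITE-seq generator
#'
#' Builds and validates the parameter set for [generate_multimodal()]. The
#' defaults emulate the sorting design of a fetal-liver HSC CITE-seq
#' experiment: a `bulk` CD34+ fraction and a functionally `enriched` fraction
#' that differ in cluster composition (cluster 0 rises from 10% to 40%),
#' mouse embryonic stem cells spiked into each fraction as background-only
#' controls for antibody staining, human-mouse doublets, and one surface
#' marker (CD201) whose protein signal discriminates cluster 0 while its
#' transcript (*PROCR*) is flat across clusters.
#'
#' @param n_genes number of human genes (>= 1).
#' @param n_mouse_genes number of mouse genes carried by spike-in cells.
#' @param n_proteins number of oligo-tagged antibodies.
#' @param clusters list of clusters, each a list with `name`,
#'   `program` (integer gene indices) and `lfc` (natural-log fold effect
#'   applied to the program genes in that cluster).
#' @param base_expr per-gene baseline negative-binomial mean (length
#'   `n_genes`).
#' @param fraction_compositions named list of cluster-proportion vectors
#'   (each sums to 1).
#' @param cells_per_fraction named integer vector of loaded droplets per
#'   fraction.
#' @param protein_signal `n_proteins` x `n_clusters` matrix of mean specific
#'   ADT signal counts per cluster.
#' @param ambient_rates per-protein Poisson mean of ambient (non-specific)
#'   ADT counts; applies to every cell including mouse spike-ins.
#' @param n_spike_ins_per_fraction named integer vector of mouse spike-in
#'   cells added to each fraction.
#' @param doublet_rate probability that a loaded droplet contains a
#'   human-mouse doublet.
#' @param mito_gene_indices indices (into the human genes) of mitochondrial
#'   genes.
#' @param mito_high_fraction fraction of human singlets whose mitochondrial
#'   content is forced above 25% of their UMIs.
#' @param nb_dispersion negative-binomial size parameter `theta`
#'   (variance = mu + mu^2/theta).
#' @param library_size_log_mean,library_size_log_sd log-normal parameters of
#'   the multiplicative per-cell library-size factor (mRNA only).
#' @param mouse_gene_mean NB mean of each mouse gene in mouse cells.
#' @param discordant_protein,discordant_gene names of the marker whose ADT
#'   signal is cluster-0 informative while its mRNA is not.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#'
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 500,
                             n_mouse_genes = 50,
                             n_proteins = 7,
                             clusters = NULL,
                             base_expr = NULL,
                             fraction_compositions = list(
                               bulk     = c(0.10, 0.40, 0.30, 0.20),
                               enriched = c(0.40, 0.30, 0.20, 0.10)),
                             cells_per_fraction = c(bulk = 5000, enriched = 5000),
                             protein_signal = NULL,
                             ambient_rates = NULL,
                             n_spike_ins_per_fraction = c(bulk = 207, enriched = 188),
                             doublet_rate = 0.05,
                             mito_gene_indices = NULL,
                             mito_high_fraction = 0.10,
                             nb_dispersion = 10,
                             library_size_log_mean = 0,
                             library_size_log_sd = 0.3,
                             mouse_gene_mean = 6,
                             discordant_protein = "CD201",
                             discordant_gene = "PROCR",
                             seed = 1L) {
  cells_per_fraction <- unlist(cells_per_fraction)
  n_spike_ins_per_fraction <- unlist(n_spike_ins_per_fraction)
  ambient_rates <- unlist(ambient_rates)
  fraction_compositions <- lapply(fraction_compositions, unlist)
  if (n_genes < 1 || any(cells_per_fraction < 1))
    stop("configuration error: non-positive gene or cell counts")
  if (is.null(clusters)) clusters <- default_clusters(n_genes)
  k <- length(clusters)
  if (is.null(base_expr)) base_expr <- default_base_expr(n_genes)
  if (length(base_expr) != n_genes) stop("base_expr must have length n_genes")
  if (is.null(mito_gene_indices))
    mito_gene_indices <- seq_len(min(10, n_genes)) + 3L
  if (is.null(protein_signal)) protein_signal <- default_protein_signal(k)
  n_proteins <- nrow(protein_signal)
  if (is.null(ambient_rates))
    ambient_rates <- rep_len(c(5, 3, 3, 2, 2, 3, 4), n_proteins)
  stopifnot(ncol(protein_signal) == k, length(ambient_rates) == n_proteins)
  if (any(ambient_rates < 0) || any(protein_signal < 0))
    stop("ambient_rates and protein_signal must be non-negative")
  if (doublet_rate < 0 || doublet_rate > 1)
    stop("doublet_rate must lie in [0, 1]")
  for (nm in names(fraction_compositions)) {
    p <- fraction_compositions[[nm]]
    if (length(p) != k) stop("composition length must equal cluster count")
    if (abs(sum(p) - 1) > 1e-9)
      stop("cluster proportions for '", nm, "' must sum to 1")
    if (any(p < 0)) stop("negative cluster proportion")
  }
  if (!setequal(names(cells_per_fraction), names(fraction_compositions)))
    stop("cells_per_fraction and fraction_compositions must name the same fractions")
  if (!all(names(n_spike_ins_per_fraction) %in% names(cells_per_fraction)))
    n_spike_ins_per_fraction <-
      stats::setNames(rep_len(n_spike_ins_per_fraction, length(cells_per_fraction)),
                      names(cells_per_fraction))
  for (cl in clusters)
    if (length(cl$program) && (min(cl$program) < 1 || max(cl$program) > n_genes))
      stop("cluster program indices out of range")
  if (max(mito_gene_indices) > n_genes) stop("mito gene indices out of range")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  structure(list(
    n_genes = as.integer(n_genes), n_mouse_genes = as.integer(n_mouse_genes),
    n_proteins = as.integer(n_proteins), clusters = clusters,
    base_expr = base_expr, fraction_compositions = fraction_compositions,
    cells_per_fraction = cells_per_fraction,
    protein_signal = protein_signal, ambient_rates = ambient_rates,
    n_spike_ins_per_fraction = n_spike_ins_per_fraction,
    doublet_rate = doublet_rate, mito_gene_indices = as.integer(mito_gene_indices),
    mito_high_fraction = mito_high_fraction, nb_dispersion = nb_dispersion,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    mouse_gene_mean = mouse_gene_mean,
    discordant_protein = discordant_protein, discordant_gene = discordant_gene,
    seed = as.integer(seed)), class = "generator_config")
}

# Default HSC/MPP-style cluster programs. Gene 1 is PROCR (never in a
# program: its mRNA is flat while the CD201 protein is cluster-0 specific),
# gene 2 is CD34, gene 3 is CD38 (in the program of the most committed
# cluster so that an mRNA CD38- gate retains stem-like cells), genes 4-13
# are mitochondrial.
default_clusters <- function(n_genes) {
  stopifnot(n_genes >= 110)
  list(
    list(name = "HSC_MPP_0", program = 14:43, lfc = 1.0),
    list(name = "HSC_MPP_1", program = 44:63, lfc = 1.0),
    list(name = "HSC_MPP_2", program = 64:83, lfc = 1.0),
    list(name = "HSC_MPP_3", program = c(3L, 84:103), lfc = 1.0)
  )
}

default_base_expr <- function(n_genes) {
  mu <- rep_len(c(0.1, 0.5, 1, 2), n_genes)
  if (n_genes >= 3) {
    mu[1] <- 1.5   # PROCR: comfortably detected, identical across clusters
    mu[2] <- 3     # CD34: high everywhere (CD34+ sorted input)
    mu[3] <- 0.05  # CD38: near-silent outside its program cluster
  }
  mu
}

default_protein_signal <- function(k) {
  stopifnot(k >= 1)
  sig <- rbind(
    CD34      = rep(60, k),
    CD90      = c(40, rep(18, k - 1)),
    CD49f     = c(35, rep(18, k - 1)),
    CD133     = c(40, rep(20, k - 1)),
    CD201     = c(45, rep(15, k - 1)),
    CD164     = c(8, rep(25, k - 1)),
    IgG1_ctrl = rep(0, k)
  )
  colnames(sig) <- paste0("cluster", seq_len(k) - 1L)
  sig
}

default_gene_names <- function(n_genes, mito_idx) {
  nm <- sprintf("GENE%04d", seq_len(n_genes))
  named <- c("PROCR", "CD34", "CD38",
             rep(NA, 10),
             "RGCC", "LMNA", "VIM", "ID1", "ID3", "AHR", "KLF6", "TIPARP",
             "HES1", "MLLT3", "HLF", "MECOM", "LMO2", "HMGA2")
  keep <- !is.na(named) & seq_along(named) <= n_genes
  nm[which(keep)] <- named[keep]
  nm[mito_idx] <- sprintf("MT-%02d", seq_along(mito_idx))
  nm
}

#' Generate a synthetic multimodal CITE-seq dataset with known ground truth
#'
#' Human cells receive negative-binomial mRNA counts with cluster-specific
#' means (`variance = mu + mu^2/theta`) and ADT counts that are the sum of an
#' NB specific-signal draw (mean set by the cell's cluster) and a Poisson
#' ambient draw. Mouse spike-in cells carry ambient-only ADT counts and zero
#' counts on every human gene; human-mouse doublets are the sum of one human
#' and one mouse expression vector. A configured fraction of human singlets
#' has part of its UMIs reallocated onto mitochondrial genes so that its
#' mitochondrial content exceeds 25% by construction.
#'
#' @param config a [generator_config()].
#' @return list with elements `dataset` (a [multimodal_dataset()], cluster
#'   labels and fraction in `meta`) and `truth` (per-cell `barcode`,
#'   `fraction`, `species`, `cluster`, `mito_high`, plus attributes
#'   `discordant_protein`, `discordant_gene`, `compositions`).
#' @export
generate_multimodal <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  k <- length(config$clusters)
  theta <- config$nb_dispersion
  cl_names <- vapply(config$clusters, `[[`, "", "name")
  # gene x cluster mean matrix
  mu_gk <- matrix(config$base_expr, config$n_genes, k)
  for (j in seq_len(k)) {
    pr <- config$clusters[[j]]$program
    mu_gk[pr, j] <- mu_gk[pr, j] * exp(config$clusters[[j]]$lfc)
  }
  gene_names <- default_gene_names(config$n_genes, config$mito_gene_indices)
  mouse_names <- sprintf("mm10-Gene%03d", seq_len(config$n_mouse_genes))

  rna_blocks <- list(); adt_blocks <- list(); truth_blocks <- list()
  cell_counter <- 0L
  for (frac in names(config$cells_per_fraction)) {
    n <- config$cells_per_fraction[[frac]]
    n_spike <- config$n_spike_ins_per_fraction[[frac]]
    comp <- config$fraction_compositions[[frac]]

    is_doublet <- stats::runif(n) < config$doublet_rate
    cluster <- sample.int(k, n, replace = TRUE, prob = comp)
    libf <- stats::rlnorm(n, config$library_size_log_mean, config$library_size_log_sd)

    mu_cells <- mu_gk[, cluster, drop = FALSE] *
      rep(libf, each = config$n_genes)
    human_rna <- matrix(stats::rnbinom(length(mu_cells), size = theta, mu = mu_cells),
                        config$n_genes, n)

    n_all <- n + n_spike
    mouse_rna <- matrix(0L, config$n_mouse_genes, n_all)
    mouse_cols <- c(which(is_doublet), n + seq_len(n_spike))
    if (length(mouse_cols) && config$n_mouse_genes > 0)
      mouse_rna[, mouse_cols] <-
        stats::rnbinom(config$n_mouse_genes * length(mouse_cols),
                       size = theta, mu = config$mouse_gene_mean)

    # force >25% mitochondrial content on a subset of human singlets; the
    # remaining cells keep their natural (low) mitochondrial share, so their
    # NB marginals are untouched
    singlets <- which(!is_doublet)
    n_high <- floor(config$mito_high_fraction * length(singlets))
    high_cells <- if (n_high > 0) sort(sample(singlets, n_high)) else integer(0)
    for (cc in high_cells) {
      target <- stats::runif(1, 0.30, 0.55)
      human_rna[, cc] <- reallocate_mito(human_rna[, cc],
                                         config$mito_gene_indices, target,
                                         high = TRUE)
    }

    # ADT: NB specific signal + Poisson ambient (ambient for every cell)
    p <- config$n_proteins
    sig_mu <- config$protein_signal[, cluster, drop = FALSE]
    adt <- matrix(0, p, n_all)
    adt[, seq_len(n)] <- stats::rnbinom(p * n, size = theta, mu = sig_mu)
    adt <- adt + matrix(stats::rpois(p * n_all, config$ambient_rates), p, n_all)

    rna <- rbind(cbind(human_rna, matrix(0L, config$n_genes, n_spike)), mouse_rna)
    species <- c(ifelse(is_doublet, "doublet", "human"), rep("mouse", n_spike))
    clab <- c(cl_names[cluster], rep(NA_character_, n_spike))
    mito_high <- c(seq_len(n) %in% high_cells & !is_doublet, rep(FALSE, n_spike))
    bc <- sprintf("%s_%06d", frac, cell_counter + seq_len(n_all))
    cell_counter <- cell_counter + n_all

    colnames(rna) <- bc; colnames(adt) <- bc
    rna_blocks[[frac]] <- rna
    adt_blocks[[frac]] <- adt
    truth_blocks[[frac]] <- data.frame(
      barcode = bc, fraction = frac, species = species, cluster = clab,
      mito_high = mito_high, stringsAsFactors = FALSE)
  }

  rna <- do.call(cbind, rna_blocks)
  adt <- do.call(cbind, adt_blocks)
  truth <- do.call(rbind, truth_blocks)
  rownames(truth) <- NULL
  rownames(rna) <- c(gene_names, mouse_names)
  rownames(adt) <- rownames(config$protein_signal)

  features <- data.frame(
    id = c(gene_names, mouse_names, paste0("ADT-", rownames(adt))),
    name = c(gene_names, mouse_names, rownames(adt)),
    species = c(rep("human", config$n_genes), rep("mouse", config$n_mouse_genes),
                rep("human", config$n_proteins)),
    type = c(rep("gene", config$n_genes + config$n_mouse_genes),
             rep("antibody", config$n_proteins)),
    stringsAsFactors = FALSE)
  meta <- truth[, c("barcode", "fraction", "cluster")]
  dataset <- multimodal_dataset(Matrix::Matrix(rna, sparse = TRUE), adt,
                                features, meta)
  attr(truth, "discordant_protein") <- config$discordant_protein
  attr(truth, "discordant_gene") <- config$discordant_gene
  attr(truth, "compositions") <- config$fraction_compositions
  attr(truth, "cluster_names") <- cl_names
  list(dataset = dataset, truth = truth)
}

# Move counts so that the mitochondrial share of a cell's UMIs hits `target`
# (ceiling for forced-high cells so the share strictly exceeds 25%, floor
# otherwise so it stays at or below the target). Total UMIs are preserved.
reallocate_mito <- function(x, mito_idx, target, high) {
  total <- sum(x)
  if (total == 0) return(x)
  m <- if (high) ceiling(target * total) else floor(target * total)
  m <- min(m, total)
  non_idx <- setdiff(seq_along(x), mito_idx)
  x[mito_idx] <- as.vector(stats::rmultinom(1, m, rep(1, length(mito_idx))))
  pr <- x[non_idx]
  if (sum(pr) == 0) pr <- rep(1, length(non_idx))
  x[non_idx] <- as.vector(stats::rmultinom(1, total - m, pr))
  x
}

#' Write a generated dataset to disk as plain-text fixture files
#'
#' Emits the 10x CellRanger dialect for the mRNA modality (MatrixMarket
#' `matrix.mtx` with 1-based indices, `features.tsv`, `barcodes.tsv`), the
#' ADT counts as CSV (rows = antibodies, columns = barcodes) and the ground
#' truth as TSV. The file set round-trips losslessly through
#' [read_fixture()].
#'
#' @param dataset a `multimodal_dataset`
#' @param truth truth table as returned by [generate_multimodal()]
#' @param directory output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_fixture <- function(dataset, truth, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  genes <- dataset$features[dataset$features$type == "gene", ]
  paths <- file.path(directory,
                     c("matrix.mtx", "features.tsv", "barcodes.tsv",
                       "adt.csv", "truth.tsv"))
  Matrix::writeMM(dataset$rna, paths[1])
  utils::write.table(
    data.frame(genes$id, genes$name, "Gene Expression"),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(dataset$barcodes, paths[3])
  adt_df <- data.frame(antibody = rownames(dataset$adt), dataset$adt,
                       check.names = FALSE)
  utils::write.csv(adt_df, paths[4], row.names = FALSE, quote = FALSE)
  tr <- truth
  attr_cols <- c("discordant_protein", "discordant_gene")
  for (a in attr_cols) attr(tr, a) <- NULL
  utils::write.table(tr, paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
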