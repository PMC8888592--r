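#' Default HSC enrichment signature definitions
#'
#' Three in silico sorting strategies over a CD34+CD38- pre-gate:
#' \describe{
#'   \item{classical}{CD34+ CD38- CD90+ CD49f+ — the CD90/CD49f positive
#'     fractions default to placeholder flow-guided quantiles (top 25% and
#'     top 40% of the surviving cells, about 10% combined)}
#'   \item{Sumide}{CD34+ CD38- GPI-80(score)+ CD133+ — GPI-80 identity is a
#'     module score (top 3% of CD34+CD38- cells), CD133 the top half}
#'   \item{EPCR}{CD34+ CD38- CD201+ — CD201 the top 10%}
#' }
#' CD38- is an mRNA gate (`raw count <= cd38_max`) because the CD38 ADT is
#' assumed unusable. All fractions are configurable.
#'
#' @param cd38_max maximum raw CD38 transcript count (default 0)
#' @param cd90_top,cd49f_top,cd133_top,cd201_top,gpi80_top positive-gate
#'   fractions
#' @return named list of [signature_definition()] objects
#' @export
default_signatures <- function(cd38_max = 0, cd90_top = 0.25,
                               cd49f_top = 0.40, cd133_top = 0.50,
                               cd201_top = 0.10, gpi80_top = 0.03) {
  pre <- list(
    gate_spec("adt_corrected", "CD34", "positive_after_background"),
    gate_spec("mrna_count", "CD38", "max_count_negative", cd38_max))
  list(
    classical = signature_definition("classical", c(pre, list(
      gate_spec("adt_corrected", "CD90", "top_fraction", cd90_top),
      gate_spec("adt_corrected", "CD49f", "top_fraction", cd49f_top)))),
    Sumide = signature_definition("Sumide", c(pre, list(
      gate_spec("module_score", "GPI80", "top_fraction", gpi80_top),
      gate_spec("adt_corrected", "CD133", "top_fraction", cd133_top)))),
    EPCR = signature_definition("EPCR", c(pre, list(
      gate_spec("adt_corrected", "CD201", "top_fraction", cd201_top))))
  )
}

#' Assemble and validate a pipeline configuration
#'
#' @param simulate a [generator_config()] to generate the input, or `NULL`
#' @param input_dir fixture directory ([write_fixture()] layout) to read
#'   when `simulate` is `NULL`
#' @param output_dir where stage outputs and the manifest are written
#' @param qc,adt,score,gpi80,enrichment,de stage parameter lists (see
#'   defaults in the function signature)
#' @param signatures named list of [signature_definition()]s; default
#'   [default_signatures()]
#' @param seed integer seed for every stochastic stage
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL, output_dir,
                            qc = list(mito_max = 0.25, species_high = 0.9,
                                      species_low = 0.1),
                            adt = list(n_sd = 1),
                            score = list(scale = 1e4, nbin = 24, n_ctrl = 100),
                            gpi80 = list(top_fraction = 0.0237,
                                         n_top_genes = 30),
                            enrichment = list(levels = c(1, 0.5, 0.25, 0.10, 0.05),
                                              level = 0.05,
                                              target_cluster = NULL),
                            de = list(alpha = 0.05, lfc_min = 0.25,
                                      min_pct = 0.10),
                            signatures = default_signatures(),
                            seed = 1L) {
  if (is.null(simulate) && is.null(input_dir))
    stop("either simulate or input_dir must be given")
  structure(list(simulate = simulate, input_dir = input_dir,
                 output_dir = output_dir, qc = qc, adt = adt, score = score,
                 gpi80 = gpi80, enrichment = enrichment, de = de,
                 signatures = signatures, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Covers the scalar stage parameters and signature definitions; a
#' `simulate: default: true` entry requests the default generator (with any
#' listed overrides applied).
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    args <- raw$simulate
    args$default <- NULL
    sim <- do.call(generator_config, args)
  }
  sigs <- if (is.null(raw$signatures)) default_signatures() else
    lapply(stats::setNames(nm = names(raw$signatures)), function(nm)
      signature_definition(nm, lapply(raw$signatures[[nm]], function(g)
        gate_spec(g$axis, g$marker, g$mode,
                  if (is.null(g$parameter)) NA_real_ else g$parameter))))
  args <- raw[intersect(names(raw), c("input_dir", "output_dir", "qc", "adt",
                                      "score", "gpi80", "enrichment", "de",
                                      "seed"))]
  do.call(pipeline_config, c(list(simulate = sim, signatures = sigs), args))
}

# every marker a config references must resolve against the dataset
validate_config_markers <- function(config, dataset) {
  adt_names <- rownames(dataset$adt)
  gene_names <- dataset$features$id[dataset$features$type == "gene"]
  for (sig in config$signatures) for (g in sig$gates) {
    known <- switch(g$axis,
                    adt_corrected = g$marker %in% adt_names,
                    mrna_count = g$marker %in% gene_names,
                    module_score = TRUE)  # scores are computed in-run
    if (!known)
      stop("configuration references unknown marker '", g$marker,
           "' on axis ", g$axis)
  }
  invisible(TRUE)
}

#' Run the full multimodal analysis pipeline
#'
#' Chains every stage — input (generate or read), QC, per-fraction ADT
#' processing, normalization and scoring, in silico sorting, enrichment and
#' cluster dynamics, differential expression and signature comparison — and
#' writes each stage's output plus a JSON run manifest recording versions,
#' seeds and every applied threshold. Any stage failure aborts with the
#' stage name.
#'
#' The two fractions are interpreted positionally: the first fraction name
#' (in `meta$fraction` order of appearance) is the bulk/reference fraction,
#' the second the functionally enriched one.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress progress messages
#' @return invisibly, a list with every stage result (`dataset`, `truth`,
#'   `qc`, `adt`, `scores`, `sorts`, `overlap_cells`, `enrichment`,
#'   `dynamics`, `phases`, `de`, `overlap_degs`, `ranks`, `manifest`)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[citesort] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # ---- input ----
  truth <- NULL
  if (!is.null(config$simulate)) {
    say("generating synthetic input (seed ", config$simulate$seed, ")")
    gen <- stage("input", generate_multimodal(config$simulate))
    dataset <- gen$dataset; truth <- gen$truth
  } else {
    say("reading fixture from ", config$input_dir)
    fx <- stage("input", read_fixture(config$input_dir))
    dataset <- fx$dataset; truth <- fx$truth
  }
  stage("validate", validate_config_markers(config, dataset))
  fractions <- unique(dataset$meta$fraction)
  if (length(fractions) < 2)
    stop("pipeline stage 'validate' failed: need at least two fractions")
  bulk <- fractions[1]; enriched <- fractions[2]

  # ---- qc ----
  say("QC: species assignment, doublet rate, mitochondrial filter")
  qc <- stage("qc", qc_report(dataset, mito_max = config$qc$mito_max,
                              species_high = config$qc$species_high,
                              species_low = config$qc$species_low))
  keep <- qc$cells$pass

  # ---- adt ----
  say("ADT: per-fraction CLR, spike-in background, subtraction")
  adt <- stage("adt", process_adt(dataset, qc$cells$species,
                                  human_keep = keep,
                                  n_sd = config$adt$n_sd))

  # ---- expression + scores ----
  say("scores: log-normalization, GPI-80 module score, cell-cycle phases")
  human <- stage("score", subset_cells(dataset, keep))
  genes_h <- human$features$id[human$features$type == "gene" &
                                 human$features$species == "human"]
  expr <- stage("score", log_normalize(human$rna[genes_h, , drop = FALSE],
                                       scale = config$score$scale))
  in_bulk <- human$meta$fraction == bulk
  in_enr <- human$meta$fraction == enriched
  de_fraction <- stage("score", differential_expression(
    expr, in_enr, alpha = config$de$alpha, lfc_min = config$de$lfc_min,
    min_pct = config$de$min_pct))
  top_genes <- utils::head(de_fraction$gene[de_fraction$lfc > 0],
                           config$gpi80$n_top_genes)
  cd34_pos <- adt$corrected["CD34", human$barcodes] > 0
  gpi <- stage("score", gpi80_score(
    expr, top_genes, cd34_pos, top_fraction = config$gpi80$top_fraction,
    nbin = config$score$nbin, n_ctrl = config$score$n_ctrl,
    seed = config$seed))
  cc <- stage("score", cell_cycle_call_for(expr, config))

  # ---- gating (within the bulk fraction, as sorting starts from bulk) ----
  say("gating: in silico sorting of ", length(config$signatures),
      " signatures")
  axes <- list(
    adt_corrected = adt$corrected,
    mrna_count = as.matrix(human$rna[genes_h, , drop = FALSE]),
    module_score = list(GPI80 = gpi$score$score))
  bulk_bc <- human$barcodes[in_bulk]
  sorts <- stage("gate", lapply(config$signatures, sort_signature,
                                axes = axes, within = bulk_bc))
  overlap_cells <- stage("gate", signature_overlap_cells(sorts))

  # ---- enrichment ----
  target <- config$enrichment$target_cluster
  if (is.null(target)) target <- sort(unique(human$meta$cluster))[1]
  say("enrichment: curves and cluster dynamics (target ", target, ")")
  curves <- stage("enrich", lapply(
    stats::setNames(nm = rownames(adt$corrected)), function(m)
      enrichment_curve(adt$corrected[m, bulk_bc],
                       human$meta$cluster[in_bulk], target,
                       levels = config$enrichment$levels, marker = m)))
  markers_at_level <- stage("enrich", marker_comparison(
    adt$corrected[, bulk_bc, drop = FALSE], human$meta$cluster[in_bulk],
    target, level = config$enrichment$level))
  dynamics <- stage("enrich", cluster_dynamics(
    human$meta$cluster[in_bulk], human$meta$cluster[in_enr]))
  phases <- stage("enrich", phase_composition(cc$phase, human$meta$fraction))

  # ---- de_compare ----
  say("DE: per-signature differential expression and overlap")
  de_tabs <- stage("de", lapply(sorts, function(s)
    differential_expression(expr[, in_bulk, drop = FALSE],
                            bulk_bc %in% s$selected,
                            alpha = config$de$alpha,
                            lfc_min = config$de$lfc_min,
                            min_pct = config$de$min_pct)))
  sets <- lapply(de_tabs, deg_genes, direction = "up")
  ref <- if ("Sumide" %in% names(sets)) "Sumide" else names(sets)[1]
  overlap_degs <- stage("compare", overlap_report(sets, reference = ref))
  ranks <- stage("compare", suppressWarnings(
    rank_table(de_tabs, reference = ref, top_n = 25)))

  # ---- write outputs + manifest ----
  say("writing outputs to ", out_dir)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(qc$cells, "qc_cells.tsv")
  wt(qc$summary, "qc_summary.tsv")
  wt(do.call(rbind, adt$background), "adt_background.tsv")
  wt(data.frame(barcode = human$barcodes, fraction = human$meta$fraction,
                cluster = human$meta$cluster, gpi80_score = gpi$score$score,
                phase = cc$phase), "cell_scores.tsv")
  wt(do.call(rbind, lapply(sorts, function(s)
    data.frame(signature = s$name, barcode = s$selected))), "sorted_cells.tsv")
  wt(do.call(rbind, lapply(names(curves), function(m)
    cbind(marker = m, as.data.frame(curves[[m]])))), "enrichment_curves.tsv")
  wt(markers_at_level, "marker_comparison.tsv")
  wt(as.data.frame(dynamics), "cluster_dynamics.tsv")
  wt(phases, "phase_composition.tsv")
  for (nm in names(de_tabs)) wt(de_tabs[[nm]], paste0("deg_", nm, ".tsv"))
  wt(ranks, "rank_table.tsv")

  manifest <- list(
    package = "citesort",
    version = as.character(utils::packageVersion("citesort")),
    seed = config$seed,
    fractions = list(bulk = bulk, enriched = enriched),
    n_cells_input = length(dataset$barcodes),
    n_cells_pass_qc = sum(keep),
    doublet_rate = as.list(qc$doublet_rate),
    thresholds = list(
      qc = config$qc, adt = config$adt, score = config$score,
      gpi80 = config$gpi80, de = config$de,
      gates = lapply(sorts, `[[`, "thresholds")),
    pass_counts = lapply(sorts, function(s) as.list(s$pass_counts)),
    deg_overlap_pct = as.list(overlap_degs$shared_pct),
    simulate = if (!is.null(config$simulate))
      list(seed = config$simulate$seed,
           cells_per_fraction = as.list(config$simulate$cells_per_fraction),
           doublet_rate = config$simulate$doublet_rate))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, truth = truth, qc = qc, adt = adt,
                 expr = expr, de_fraction = de_fraction, gpi80 = gpi,
                 cell_cycle = cc, sorts = sorts,
                 overlap_cells = overlap_cells, curves = curves,
                 marker_comparison = markers_at_level, dynamics = dynamics,
                 phases = phases, de = de_tabs, overlap_degs = overlap_degs,
                 ranks = ranks, manifest = manifest))
}

# Cell-cycle call: use configured gene lists when given, otherwise the
# shipped Tirosh lists intersected with the dataset's genes; with no usable
# genes every cell is called G1.
cell_cycle_call_for <- function(expr, config) {
  s_genes <- config$score$s_genes
  g2m_genes <- config$score$g2m_genes
  if (is.null(s_genes) || is.null(g2m_genes)) {
    cc <- cell_cycle_genes()
    s_genes <- intersect(cc$s_genes, rownames(expr))
    g2m_genes <- intersect(cc$g2m_genes, rownames(expr))
  }
  if (length(s_genes) == 0 || length(g2m_genes) == 0) {
    zero <- stats::setNames(rep(0, ncol(expr)), colnames(expr))
    return(cell_cycle_phase(zero, zero))
  }
  s <- module_score(expr, s_genes, nbin = config$score$nbin,
                    n_ctrl = config$score$n_ctrl, seed = config$seed)
  g2m <- module_score(expr, g2m_genes, nbin = config$score$nbin,
                      n_ctrl = config$score$n_ctrl, seed = config$seed + 1L)
  cell_cycle_phase(s, g2m)
}
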