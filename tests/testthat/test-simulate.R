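test_that("identical config and seed give byte-identical output", {
  cfg <- small_config(n_bulk = 150, n_enriched = 150, n_spike = 20)
  a <- generate_multimodal(cfg)
  b <- generate_multimodal(cfg)
  expect_identical(as.matrix(a$dataset$rna), as.matrix(b$dataset$rna))
  expect_identical(a$dataset$adt, b$dataset$adt)
  expect_identical(a$truth, b$truth)
})

test_that("degenerate configurations behave as declared", {
  # no doublets, no spike-ins -> human singlets only
  cfg <- small_config(n_bulk = 100, n_enriched = 100, n_spike = 0,
                      doublet_rate = 0)
  g <- generate_multimodal(cfg)
  expect_true(all(g$truth$species == "human"))

  # zero ambient -> spike-in ADT counts exactly zero
  cfg0 <- small_config(n_bulk = 100, n_enriched = 100, n_spike = 20,
                       ambient_rates = rep(0, 7))
  g0 <- generate_multimodal(cfg0)
  spikes <- g0$truth$species == "mouse"
  expect_true(all(g0$dataset$adt[, spikes] == 0))

  # invalid configurations are rejected up front
  expect_error(generator_config(n_genes = 0), "non-positive")
  expect_error(small_config(doublet_rate = 1.5), "doublet_rate")
  expect_error(generator_config(
    fraction_compositions = list(bulk = c(0.5, 0.4, 0.05, 0.04),
                                 enriched = c(0.4, 0.3, 0.2, 0.1))),
    "sum to 1")
})

test_that("mouse cells carry no counts on human genes", {
  g <- generate_multimodal(small_config(n_bulk = 120, n_enriched = 120,
                                        n_spike = 25))
  genes <- g$dataset$features
  human_genes <- genes$id[genes$type == "gene" & genes$species == "human"]
  mouse_cells <- g$truth$species == "mouse"
  expect_equal(sum(g$dataset$rna[human_genes, mouse_cells]), 0)
  # and doublets carry counts on both references
  dbl <- which(g$truth$species == "doublet")
  mouse_genes <- genes$id[genes$type == "gene" & genes$species == "mouse"]
  expect_true(all(Matrix::colSums(g$dataset$rna[human_genes, dbl]) > 0))
  expect_true(all(Matrix::colSums(g$dataset$rna[mouse_genes, dbl]) > 0))
})

test_that("empirical cluster proportions match the configured composition", {
  # binomial oracle at the configured n: |p_hat - p| < 3 sqrt(p(1-p)/n)
  cfg <- small_config(n_bulk = 2000, n_enriched = 2000, n_spike = 0,
                      doublet_rate = 0, seed = 11)
  g <- generate_multimodal(cfg)
  for (frac in c("bulk", "enriched")) {
    p <- cfg$fraction_compositions[[frac]][1]
    lab <- g$truth$cluster[g$truth$fraction == frac]
    phat <- mean(lab == "HSC_MPP_0")
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / length(lab)))
  }
})

test_that("NB marginal means converge to the configured means", {
  cfg <- generator_config(
    cells_per_fraction = c(bulk = 5000, enriched = 100),
    fraction_compositions = list(bulk = c(1, 0, 0, 0),
                                 enriched = c(1, 0, 0, 0)),
    n_spike_ins_per_fraction = c(bulk = 0, enriched = 0),
    doublet_rate = 0, mito_high_fraction = 0,
    library_size_log_sd = 0, seed = 5)
  g <- generate_multimodal(cfg)
  bulk <- g$truth$fraction == "bulk"
  mu <- cfg$base_expr
  mu[cfg$clusters[[1]]$program] <- mu[cfg$clusters[[1]]$program] *
    exp(cfg$clusters[[1]]$lfc)
  x <- as.matrix(g$dataset$rna[seq_len(cfg$n_genes), bulk])
  for (i in c(1, 2, 20, 100, 250, 500)) {
    se <- stats::sd(x[i, ]) / sqrt(sum(bulk))
    expect_lt(abs(mean(x[i, ]) - mu[i]), 3 * se + 1e-12)
  }
})

test_that("the discordant marker is protein-informative but mRNA-flat", {
  g <- generate_multimodal(small_config(n_bulk = 1000, n_enriched = 1000,
                                        n_spike = 0, doublet_rate = 0,
                                        library_size_log_sd = 0, seed = 3))
  tr <- g$truth
  gene <- attr(tr, "discordant_gene")
  prot <- attr(tr, "discordant_protein")
  in0 <- tr$cluster == "HSC_MPP_0"
  rna <- as.numeric(g$dataset$rna[gene, ])
  diff_rna <- mean(rna[in0]) - mean(rna[!in0])
  se <- sqrt(stats::var(rna[in0]) / sum(in0) + stats::var(rna[!in0]) / sum(!in0))
  expect_lt(abs(diff_rna), 3 * se)          # configured null effect
  adt <- g$dataset$adt[prot, ]
  se_adt <- sqrt(stats::var(adt[in0]) / sum(in0) +
                 stats::var(adt[!in0]) / sum(!in0))
  expect_gt(mean(adt[in0]) - mean(adt[!in0]), 3 * se_adt)  # positive effect
})

test_that("fixtures round-trip losslessly and deterministically", {
  cfg <- generator_config(
    n_genes = 120, n_mouse_genes = 10,
    cells_per_fraction = c(bulk = 100, enriched = 100),
    n_spike_ins_per_fraction = c(bulk = 10, enriched = 10), seed = 9)
  g <- generate_multimodal(cfg)
  dir1 <- withr::local_tempdir()
  paths <- write_fixture(g$dataset, g$truth, dir1)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))

  back <- read_fixture(dir1)
  expect_equal(as.matrix(back$dataset$rna), as.matrix(g$dataset$rna))
  expect_equal(back$dataset$adt, g$dataset$adt)
  expect_identical(back$truth$cluster, g$truth$cluster)

  # double run with the same seed -> identical checksums
  dir2 <- withr::local_tempdir()
  write_fixture(generate_multimodal(cfg)$dataset,
                generate_multimodal(cfg)$truth, dir2)
  for (f in basename(paths))
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
})
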