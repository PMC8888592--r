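toy_values <- function(v, bc = sprintf("c%03d", seq_along(v))) {
  stats::setNames(v, bc)
}

test_that("top-fraction gates select exactly ceiling(f * n) cells", {
  v <- toy_values(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  got <- apply_gate(v, gate_spec("adt_corrected", "A", "top_fraction", 0.2),
                    names(v))
  expect_identical(got, c("c001", "c002"))
  # f = 1 leaves the set unchanged
  expect_identical(
    apply_gate(v, gate_spec("adt_corrected", "A", "top_fraction", 1),
               names(v)),
    names(v))
  # adversarially tied values: size is still ceiling(f * n), and the stable
  # tie-break keeps the lowest barcodes
  tied <- toy_values(rep(5, 10))
  for (f in c(0.11, 0.25, 0.3, 0.5, 0.77, 1)) {
    got <- apply_gate(tied, gate_spec("adt_corrected", "A", "top_fraction", f),
                      names(tied))
    expect_length(got, ceiling(f * 10))
    expect_identical(got, sort(names(tied))[seq_len(ceiling(f * 10))])
  }
  # f * n < 1 selects nothing, with a warning
  expect_warning(
    none <- apply_gate(toy_values(1:5),
                       gate_spec("adt_corrected", "A", "top_fraction", 0.1),
                       sprintf("c%03d", 1:5)),
    "no cells")
  expect_length(none, 0)
})

test_that("threshold gate modes implement their predicates", {
  v <- toy_values(c(0, 0.5, 2, 0))
  expect_identical(
    apply_gate(v, gate_spec("adt_corrected", "A", "positive_after_background"),
               names(v)),
    c("c002", "c003"))
  # a vacuous negative gate passes everything
  zero <- toy_values(rep(0, 4))
  expect_identical(
    apply_gate(zero, gate_spec("mrna_count", "CD38", "max_count_negative", 0),
               names(zero)),
    names(zero))
  expect_identical(
    apply_gate(v, gate_spec("module_score", "S", "absolute_threshold", 0.5),
               names(v)),
    c("c002", "c003"))
  expect_error(gate_spec("adt_corrected", "A", "top_fraction", 1.2), "0, 1")
  expect_error(gate_spec("adt_corrected", "A", "max_count_negative", -1),
               ">= 0")
})

test_that("gate chains are conjunctive, ordered and monotone", {
  # hand-enumerated chain: 100 cells, threshold keeps 40, top-20% keeps 8
  bc <- sprintf("c%03d", 1:100)
  marker1 <- toy_values(c(rep(1, 40), rep(0, 60)), bc)
  marker2 <- toy_values(c(100:1), bc)
  sig <- signature_definition("toy", list(
    gate_spec("adt_corrected", "M1", "absolute_threshold", 1),
    gate_spec("adt_corrected", "M2", "top_fraction", 0.2)))
  axes <- list(adt_corrected = rbind(M1 = marker1, M2 = marker2))
  res <- sort_signature(sig, axes)
  expect_identical(unname(res$pass_counts), c(40L, 8L))
  expect_identical(res$selected, bc[1:8])  # the 8 largest M2 among the 40
  # monotone: every prefix of the chain is a superset of the full selection
  prefix <- sort_signature(signature_definition("p", sig$gates[1]), axes)
  expect_true(all(res$selected %in% prefix$selected))
  expect_true(length(res$selected) <= length(prefix$selected))
  # single top-fraction 1.0 gate returns all input cells
  all_sig <- signature_definition("all", list(
    gate_spec("adt_corrected", "M1", "top_fraction", 1)))
  expect_identical(sort_signature(all_sig, axes)$selected, bc)
  # unknown markers propagate the failing gate index
  bad <- signature_definition("bad", list(
    gate_spec("adt_corrected", "NOPE", "top_fraction", 0.5)))
  expect_error(sort_signature(bad, axes), "gate 1.*NOPE")
})

test_that("random gate chains never enlarge the selection", {
  set.seed(23)
  bc <- sprintf("c%03d", 1:80)
  axes <- list(adt_corrected = matrix(runif(3 * 80), 3, 80,
                                      dimnames = list(c("A", "B", "C"), bc)))
  for (i in 1:10) {
    fs <- runif(3, 0.1, 1)
    sig <- signature_definition("r", list(
      gate_spec("adt_corrected", "A", "top_fraction", fs[1]),
      gate_spec("adt_corrected", "B", "top_fraction", fs[2]),
      gate_spec("adt_corrected", "C", "top_fraction", fs[3])))
    res <- sort_signature(sig, axes)
    expect_true(all(diff(res$pass_counts) <= 0))
    expect_true(all(res$selected %in% bc))
  }
})

test_that("signature overlap reports intersections by barcode", {
  mk <- function(name, sel) structure(
    list(name = name, selected = sel, pass_counts = length(sel),
         thresholds = list(), n_input = 10),
    class = "sort_result")
  same <- signature_overlap_cells(list(mk("x", c("a", "b")), mk("y", c("a", "b"))))
  expect_setequal(same$common, c("a", "b"))
  tri <- signature_overlap_cells(list(
    mk("x", c("a", "b", "c")), mk("y", c("b", "c", "d")),
    mk("z", c("c", "d", "e"))))
  expect_identical(tri$common, "c")
  expect_identical(tri$n_common, 1L)
  expect_equal(tri$pairwise$n_intersect, c(2L, 1L, 2L))
})

test_that("random-selection triple overlap matches the hypergeometric mean", {
  # three independent k-of-n draws: E|triple intersection| = k^3 / n^2
  n <- 100; k <- 20
  universe <- sprintf("c%03d", 1:n)
  set.seed(101)
  sizes <- replicate(200, {
    sel <- lapply(1:3, function(i) sample(universe, k))
    length(Reduce(intersect, sel))
  })
  expected <- k^3 / n^2
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})
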