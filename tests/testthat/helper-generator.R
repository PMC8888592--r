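# Small generator configurations shared across test files. Sizes are kept
# small where the property under test allows it; sampling-oracle tests state
# their own n.

small_config <- function(n_bulk = 400, n_enriched = 400, n_spike = 40,
                         doublet_rate = 0.05, seed = 42, ...) {
  generator_config(
    cells_per_fraction = c(bulk = n_bulk, enriched = n_enriched),
    n_spike_ins_per_fraction = c(bulk = n_spike, enriched = n_spike),
    doublet_rate = doublet_rate, seed = seed, ...)
}

# scalar CLR oracle: the per-ADT formula evaluated entry by entry
clr_oracle <- function(x) {
  g <- exp(sum(log(1 + x[x > 0])) / length(x))
  log(1 + x / g)
}
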