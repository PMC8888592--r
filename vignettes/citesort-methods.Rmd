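---
title: "citesort: methods and design notes"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citesort)
```

# Scope

`citesort` analyzes paired single-cell measurements — a sparse mRNA count
matrix and an antibody-derived-tag (ADT) count matrix over the same cell
barcodes — produced by CITE-seq experiments in which sorted cell fractions
(a bulk CD34+ fraction and a functionally enriched fraction) are profiled
together with mouse spike-in cells that act as antibody-background
controls. The package covers quality control, spike-in-calibrated ADT
processing, gene-module scoring, FACS-style in silico sorting, enrichment
quantification and differential-expression-based signature comparison. It
deliberately does *not* cluster cells or compute embeddings: cluster labels
are an exchangeable input (from any external clustering, or from the
synthetic generator's ground truth), so the methods here are testable
independently of any particular clustering algorithm.

# The ADT model

## CLR transform

ADT counts are compositional: a cell's tag counts compete for sequencing
depth. Per antibody (the "margin 1" orientation), the count vector $x$ over
all cells of one fraction is transformed as

$$y_c = \ln\!\left(1 + \frac{x_c}{g}\right), \qquad
  g = \exp\!\left(\frac{\sum_{x_c > 0}\ln(1+x_c)}{n_\text{cells}}\right).$$

Two details of this dialect are deliberate and unit-tested against a scalar
oracle:

- the geometric-mean accumulates $\ln(1+x)$ over **non-zero** entries but
  divides by the **total** number of cells (so an all-zero antibody maps to
  an all-zero row rather than NaN), matching the behaviour of the widely
  used single-cell toolchain this transform is borrowed from;
- the transform is applied jointly over the human cells *and* the mouse
  spike-ins of one fraction, because the background model must live on the
  same scale as the cells it corrects.

## Spike-in background model

Mouse spike-in cells cannot carry specific signal for human surface
markers, so their CLR values estimate non-specific staining plus ambient
tags. Per antibody the model records the spike-in mean and sample standard
deviation (n−1 denominator; at least two spike-ins are required, otherwise
the fit errors) and defines

$$\text{cutoff} = \text{mean} + 1\cdot\text{SD}.$$

Corrected abundance in human cells is $\max(0, y - \text{cutoff})$. The
floor at zero is a package decision: a "negative surface abundance" has no
physical meaning, and the floor makes `positive_after_background` gating
well-defined. Background is fitted **per fraction, never pooled** — each
fraction has its own staining batch and its own spike-ins.

The number of SDs (`n_sd = 1`) is configurable; one SD keeps roughly the
upper sixth of a Gaussian-like background above zero, which is the
operating point the cutoff convention implies.

## Outlier capping

`cap_outliers()` clamps values above the q99 quantile for display. It is
intentionally *not* part of any computation path: gating and enrichment
always run on uncapped corrected values.

# QC

Species assignment uses the human fraction of per-cell UMIs against a
joint human+mouse reference: human at ≥ 0.9, mouse at ≤ 0.1, doublet in
between. The thresholds are symmetric, configurable defaults; the empirical
doublet rate is simply the per-fraction doublet proportion. The
mitochondrial filter removes cells with **strictly more than** 25% of UMIs
on mitochondrial genes — the boundary cell passes — and QC-passing means
human *and* mito-passing. Mouse cells always fail QC but are retained up to
the ADT stage, because the background model needs them; doublets are
removed, not rescued.

# Module scores and the GPI-80 pseudo-marker

Scores follow the expression-matched-control scheme: genes are ranked by
mean normalized expression and cut into `nbin = 24` equal-frequency bins
(ranks tie-broken by gene order so binning is deterministic); each program
gene draws `n_ctrl = 100` control genes uniformly **without replacement**
from its own bin (truncated to the bin size when the bin is smaller); the
per-cell score is mean(program) − mean(pooled controls), the pooled set
keeping duplicates across program genes so each program gene contributes
equal control weight. The defaults are the conventional ones for this
procedure; both are configurable and the whole draw is seeded, so a seed
fully determines the score.

Consequences that the tests rely on:

- adding a constant to every gene of a cell leaves its score unchanged;
- a configuration in which the control pool necessarily equals the program
  set scores exactly zero;
- identical seeds give bitwise-identical scores.

Cell-cycle phase is S if the S score exceeds both the G2M score and zero,
G2M symmetrically, else G1; an exact tie goes to G1 (ties are measure-zero,
but a deterministic rule is required for reproducibility). The shipped
S/G2M lists are the published Tirosh-derived human gene lists
(`inst/extdata/cell_cycle_genes.tsv`); tests use generator-configured
lists instead, so nothing in the test suite depends on those symbols
matching synthetic gene names.

GPI-80 marks engraftable HSCs but lacks a usable ADT, and its transcript
(*VNN2*) correlates poorly with surface protein. The pseudo-marker is a
module score over the top 30 genes enriched in the functionally sorted
fraction (computed in-pipeline by Wilcoxon DE, or supplied); selection
takes the `ceiling(f · n)` top-scoring CD34+ cells with `f = 0.0237` — the
measured size of the GPI-80+ compartment within CD34+ cells — ties broken
by ascending barcode.

# The gating engine

A signature is an ordered list of gates applied conjunctively; each gate
sees only the survivors of the previous one, exactly like sequential FACS
gating, so a `top_fraction` gate takes its quantile within the surviving
population. Selection sizes are exactly `ceiling(f · n)` regardless of
ties; when `f · n < 1` the gate selects nothing and warns rather than
silently keeping one cell. The stable tie-break (ascending barcode) makes
sorted cell counts exactly reproducible.

Default signature definitions (`default_signatures()`):

- **classical** — CD34+ (corrected ADT > 0), CD38− (mRNA count ≤ 0), CD90
  top 25%, CD49f top 40%;
- **Sumide** — CD34+, CD38−, GPI-80 score top 3%, CD133 top 50%;
- **EPCR** — CD34+, CD38−, CD201 top 10%.

Two of these choices deserve comment. CD38− is an **mRNA** gate because the
CD38 antibody channel is treated as unusable (a real failure mode of
oligo-tagged CD38); the count ceiling is configurable. The positive-gate
fractions are placeholders standing in for percentages that would normally
be read off companion flow-cytometry experiments; they are config inputs,
not constants, and every applied threshold is recorded in the sort result
and the run manifest for provenance.

# Enrichment analysis

`enrichment_curve()` reports the target-cluster proportion among the top
`ceiling(f · N)` cells per level; at level 1 the value *is* the global
cluster proportion, which the tests assert exactly. Default levels
(1, 0.5, 0.25, 0.10, 0.05) cover the range down to the top-5% cut used for
per-marker comparisons; they are configurable. Enrichment always operates
on background-corrected (never raw, never capped) ADT values.
`cluster_dynamics()` reports per-cluster proportions in two fractions and
their B/A fold change, with a cluster absent from A reported as `NA` rather
than infinity.

# Differential expression and signature comparison

The per-gene test is a two-sided Wilcoxon rank-sum (normal approximation
with tie correction) on log-normalized expression. A rank test was chosen
over a hurdle-style model because it is assumption-light, well calibrated
on zero-inflated counts, and standard for single-cell marker detection;
the cost is reduced power for subtle mean shifts, acceptable here because
DEG sets feed *set-level* comparisons. Membership thresholds
(BH q < 0.05, |lfc| > 0.25, expressed in ≥ 10% of either group) are the
common single-cell defaults and are configurable. The fold change is
computed on de-logged means with a +1 pseudocount, so it is finite for
all-zero groups.

Overlap reporting is deliberately **directional**: the shared percentage of
signature A against reference R is $100\,|A \cap R| / |A|$ — each set's own
size is the denominator — while the intersection counts themselves are
symmetric. The rank table ranks significant genes by decreasing lfc and
records a reference gene missing from another signature's set as absent
(`NA`), never as rank 0.

# The synthetic generator

`generator_config()` defaults encode the study design the package targets:

- two fractions, `bulk` and `enriched`, 5000 loaded droplets each, with
  cluster compositions (0.10, 0.40, 0.30, 0.20) and (0.40, 0.30, 0.20,
  0.10) over four HSC/MPP-style clusters — cluster 0 rises fourfold, to
  40%, upon functional enrichment;
- mouse spike-ins: 207 (bulk) and 188 (enriched) cells carrying ambient-only
  ADT counts and zero counts on human genes;
- a 5% human–mouse doublet rate applied per loaded droplet;
- mRNA counts negative-binomial with mean/dispersion parameterization,
  variance $\mu + \mu^2/\theta$, $\theta = 10$ (a typical UMI-level
  dispersion); a log-normal library-size factor (sdlog 0.3) multiplies mRNA
  means but **not** ADT ambient rates, so background stays marker-specific
  as the spike-in model assumes;
- ADT counts for human cells = NB(specific signal for the cell's cluster)
  + Poisson(ambient); spike-ins are Poisson(ambient) only. Ambient
  magnitudes are free parameters (nothing pins them externally); defaults
  of 2–5 counts were chosen once as typical of ambient antibody signal and
  are not revisited;
- one discordant marker: CD201 protein signal is cluster-0 specific while
  *PROCR* mRNA belongs to no cluster program, reproducing the situation
  where protein, not transcript, identifies the functional cluster; an
  IgG-type control antibody carries no specific signal anywhere;
- 10% of human singlets have counts reallocated onto mitochondrial genes to
  a target share drawn from 30–55% (ceiling rounding), guaranteeing they
  exceed the 25% threshold, while untouched cells stay near their natural
  ~2% share — so the QC mask is recoverable exactly.

What the generator does **not** emulate: gene–gene correlation beyond
cluster programs, batch effects, empty droplets, human–human doublets,
ambient mRNA contamination, and realistic protein-distribution overlap
between immunophenotypically adjacent populations. Tests passing on this
generator therefore demonstrate correctness of the *computations* (and
recoverability of planted structure), not robustness to every artifact of
real data.

# Numerical and testing choices

- Determinism everywhere: generation, module-score control draws and the
  pipeline are seeded; RNG state is saved and restored around internal
  `set.seed()` calls so library code does not clobber a caller's stream.
- Equal-frequency binning uses `ceiling(nbin · rank / n)` with first-wins
  tie-breaking — exact equal sizes when `n` divides by `nbin`, off-by-one
  otherwise.
- Sampling-oracle tests use 3-SD/3-SE binomial bands at their stated sizes
  (2000–5000 cells for composition, doublet and enrichment recovery; 1000
  genes × 2000 cells for DE null calibration); these sizes were chosen so
  the whole suite runs in well under a minute while keeping the bands
  tight enough to catch real defects.
- `run_pipeline()` validates that every marker referenced by the
  configuration resolves against the dataset *before* any stage runs, and
  the JSON manifest records versions, seeds and every applied threshold, so
  a manifest suffices to re-run a pipeline bit-identically.

# Known limitations

- The Wilcoxon stand-in makes DEG *sets* reproducible only up to test
  choice; analyses built on hurdle-model DE will differ in the tail of the
  significance ranking.
- Default gate fractions are placeholders; reproducing a specific
  experiment's sorted cell counts requires setting them from that
  experiment's flow percentages.
- The ADT noise model (NB signal + Poisson ambient) has no per-cell
  capture-efficiency term; spike-in calibration absorbs the average effect
  but not cell-to-cell variability.
- `phase_composition()` and the cell-cycle call depend on gene lists that
  must match the dataset's gene naming; with no usable list every cell is
  conservatively called G1.
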