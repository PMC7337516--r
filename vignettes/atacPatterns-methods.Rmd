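---
title: "Methods: models, priors and design choices in atacPatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, priors and design choices in atacPatterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atacPatterns)
```

This vignette documents the statistical models implemented in atacPatterns,
the parameters that matter in practice, the numerical choices behind them,
and what the synthetic data generator does and does not emulate. It states
no empirical result beyond what the package's own tests and
`scripts/acceptance.R` compute.

## The factorization model

The input is a features × cells count matrix **C** (peaks, motifs or genes
by cells), filtered so that no feature and no cell is more than 99% zero
(`filter_sparse()`, threshold exposed). The model is

$$p(A, P \mid C, \Sigma) \propto p(C \mid A, P, \Sigma)\, p(A)\, p(P),$$

with an element-wise Gaussian likelihood: $C_{ij} \sim
\mathcal{N}((AP)_{ij}, \Sigma_{ij}^2)$. The uncertainty matrix
$\Sigma_{ij} = \max(f \cdot C_{ij}, \sigma_0)$ is a multiplicative noise
model with a floor: the defaults $f = 0.1$ (10% of the count) and
$\sigma_0 = 0.1$ keep zero counts informative without letting them dominate
the fit. Both are `factorization_config()` fields; for dense, high-count
matrices (e.g. expression counts) a larger floor downweights Poisson noise
around large means.

### Sparsity prior and Gibbs sampler

Every element of **A** and **P** carries a spike-and-slab prior: an exact
zero with probability $\pi$ (`zero_prob`, default 0.25), otherwise a gamma
slab with shape 1 (an exponential) and scale `sparsity_scale` (default 1).
The unit shape is deliberate: with an exponential slab every full
conditional is available in closed form — a Bernoulli spike/slab choice with
analytic odds followed by a truncated-normal draw — so the sampler is an
exact element-wise Gibbs sampler with no Metropolis step and no tuning.
Larger `zero_prob` yields sparser amplitude and pattern matrices
(monotonically, as checked by a property test); values much above 0.5 make
the posterior strongly multimodal and are not recommended as defaults.

The sampler runs `n_iterations` burn-in sweeps followed by `n_iterations`
sampling sweeps (default 10000 each); reported **A** and **P** are posterior
means over the sampling phase, which gives deterministic output for a fixed
seed. Two further choices matter:

- **Annealed burn-in.** The spike is disabled for the first half of burn-in.
  The dense posterior is far less multimodal, so the chain settles into the
  right basin before sparsification; without this, occasional seeds merge
  two cell populations into one pattern and leave a near-empty pattern
  behind.
- **Canonical pattern order.** Patterns are sorted by descending row sum of
  **P**, removing label-switching nondeterminism from outputs.

Initialization draws every element of **A** and **P** from the slab
(gamma(1, scale)) under the run seed; a strictly positive start avoids
absorbing states. All randomness flows through R's RNG, so a seed plus
config plus input reproduces results bit for bit.

### Goodness of fit and choosing the number of patterns

$\chi^2 = \sum_{ij} ((C - AP)_{ij}/\Sigma_{ij})^2$ is recorded along the
chain and at the posterior mean. `scan_dimensionality()` runs one seeded
factorization per candidate *n* and tabulates the final $\chi^2$; no
automatic selection is performed, because the right dimensionality is a
judgment call that should combine the fit table with prior knowledge of the
populations present (more patterns fit better but increasingly capture
single cells).

### Genome-wide (distributed) mode

`run_distributed()` partitions features uniformly at random into
`n_feature_subsets` subsets, runs an independent chain per subset, aligns
patterns across chains by greedy maximum cosine similarity of **P** rows
against the first chain, averages matched rows into a consensus **P**, and
re-estimates each feature's amplitude row against the consensus by
non-negative least squares. With one subset it is exactly `run_cogaps()`.
Greedy matching is deterministic; a subset must contain more features than
patterns.

## PatternMarker statistic

For an item with non-negative weight row $w$ (a row of **A**, or a column of
**P** for cells), the row is scaled by its maximum and scored against each
pattern's unit vector: $s_k = \lVert w/\max(w) - e_k \rVert_2$. The item is
assigned to $\arg\min_k s_k$; lower scores are more marker-like, and the
statistic is invariant to the item's overall scale. Exact ties are broken
to the lowest pattern index and flagged `ambiguous` rather than dropped;
all-zero rows are left unassigned with a warning. All features are retained
by default; `marker_features(top_k =)` truncates each pattern's ranked list
when a fixed-size marker set is wanted (e.g. for heatmaps).

## Regulatory annotation

**Peak→gene matching** links a gene to a peak when the peak overlaps the
gene body or the strand-aware promoter window, by default 1500 bp upstream
to 500 bp downstream of the TSS. The window is a convention, not a
biological constant — both flanks are exposed. Intervals are handled as
`GRanges` throughout; BED input is shifted on read so all overlap semantics
(including half-open abutment) are exact.

**Pathway overlap** is the one-sided hypergeometric upper tail with BH
correction across sets. The universe defaults to the genes mappable from
the filtered peak set — conditioning on what the assay could have detected —
and is exposed because a whole-genome universe inflates enrichment.

**Motif scanning** scores every window of each peak sequence on both strands
with log2 odds of the PWM (probabilities floored at 1e-4) against a 0-order
background estimated from the scanned sequences and symmetrized over
strands. The match threshold is calibrated so a random background sequence
exceeds it with probability at most `p_threshold` (default 5e-5), computed
exactly by dynamic programming over the discretized score distribution
(resolution 1/1000 of a log-odds unit; the scan subtracts the worst-case
rounding slack so discretization can only widen, never narrow, the match
set). When even a perfect match is more probable than `p_threshold` (short
or degenerate motifs), the threshold falls back to the maximum achievable
score, i.e. consensus-only matching. A motif counts once per peak
regardless of the number of sites.

**Fold accessibility** of a gene in a cell population is the mean, over
peaks overlapping the gene (body + promoter; a TSS-only variant is
provided), of the number of population cells with a nonzero count, divided
by the same mean over all peaks. It depends only on the zero pattern, hence
is invariant to any positive rescaling (including width normalization), and
is an approximate guide to whether a TF's own locus is open — not a precise
quantification.

## Transfer learning

`match_features()` pairs source and target peaks with any interval overlap,
reduced to a one-to-one matching greedily by descending overlap length (ties
to the lower source coordinate). The greedy reduction resolves many-to-many
overlap ambiguity deterministically; summing multi-overlapping target peaks
instead would be a reasonable alternative and is deliberately not done, to
keep the projected feature space a subset of the measured one. Motif and
id modes intersect identifiers exactly.

`project()` restricts the source amplitude matrix to matched features and
solves one ordinary least squares problem per target cell. Projection is
intentionally unconstrained: negative projected weights indicate
anti-correlation with a pattern and are preserved. Rank deficiency of the
restricted amplitude matrix is fatal, with the condition number reported.
No rescaling is applied to the target counts beyond whatever preprocessing
the caller chose. Group structure in projected weights is tested by
pairwise two-sided Wilcoxon rank-sum tests with BH correction within each
pattern (exact when both groups have ≤ 10 cells and no ties).

## Multi-omic TF validation

Genes are ranked per pattern by the negated PatternMarker distance (higher
score = more uniquely associated). Candidate TFs from the scATAC analysis
are tested by classical preranked GSEA: the weighted Kolmogorov–Smirnov
running sum with weight exponent 1 on |score|, p-values from seeded
gene-label permutations (default 10000; the observed score is compared to
null scores of the same sign), and BH correction across the tested TFs
only. Regulons with fewer than `min_size = 5` members in the ranking are
skipped and recorded — the enrichment score is unstable below that — as is
the degenerate case of a regulon covering the entire ranking. The in-package
implementation is cross-checked in the test suite against an independent
GSEA implementation (fgsea) on shared inputs.

## The synthetic data generator

`generate_atac()` emulates the structure the analysis assumes: `n_cell_types`
populations (default 3 × 30 cells), each with a disjoint block of
`marker_peaks_per_type` marker peaks (default 40 of 200) accessible at
`marker_access_prob = 0.5` in its own cells and `background_access_prob =
0.02` elsewhere; counts are Bernoulli × (1 + Poisson(1)), stored as reals
because downstream code must accept width-normalized input. Peak widths
vary (200–1000 bp) so width normalization is exercised. Each population has
a planted motif carried by 80% of its marker peaks plus uniform decoy
motifs, toy genes tile the contig, and each population's planted TF regulon
is the genes under its marker peaks. `generate_matched_rna()` over-expresses
each regulon in its own population by a log-normal fold shift (default
log 4) over a shared log-normal baseline with Poisson counts.

What it does **not** emulate: sequencing-depth variation between cells,
batch effects, doublets, fragment-length or insertion-site biases,
correlated (non-block) accessibility structure, and overlapping cell-type
programs. Passing the planted-recovery tests therefore demonstrates
correctness of the inference machinery on well-specified structure, not
performance on the harder, messier structure of real data.

## Problem sizes and tolerances

The test suite and acceptance script run factorizations at 200 peaks × 90
cells with 750 Gibbs sweeps per phase (400 for the denser RNA matrices,
with `uncertainty_floor = 0.5`), and 500 GSEA permutations — sizes chosen so
the full planted-recovery studies (10 seeds each) complete in a couple of
minutes while leaving wide margins on the recovery criteria. The package
defaults (10000 sweeps, 10000 permutations) are appropriate for real data.
Exact statistics (hypergeometric tails, ARI, exact Wilcoxon, BH) are tested
against independent enumeration oracles; sampler determinism is tested for
bit-identical output under a fixed seed.

## Known limitations

- The Gibbs sampler is single-chain per (subset, seed); it reports no
  convergence diagnostics beyond the $\chi^2$ trace. Inspect the trace when
  results look degenerate, and prefer the annealed default.
- The slab shape is fixed at 1; heavier-tailed amplitude distributions are
  absorbed by the scale parameter rather than modelled.
- Projection assumes the matched feature space measures comparable signal in
  both data sets; no cross-data-set normalization is attempted.
- Fold accessibility and the binary motif-per-peak convention discard
  within-peak quantitative signal by design.
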