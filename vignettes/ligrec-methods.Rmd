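---
title: "Methods: ligand-receptor co-expression shifts and communication networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-receptor co-expression shifts and communication networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligrec)
```

# The scientific problem

Cells coordinate through ligand-receptor signaling: a sender cell secretes
or displays a ligand, and a receiver cell responds through the cognate
receptor. A transcriptome does not observe binding events, but it does
observe whether the two transcripts are expressed, and — across a cohort of
samples or a population of single cells — whether they co-vary. `ligrec`
builds on two proxies for intercellular communication:

1. **Bulk cohorts.** If a ligand-receptor pair participates in active
   signaling in a tissue, its two transcripts tend to be positively
   correlated across samples of that tissue, because both respond to the
   abundance and activity of the communicating cell populations. A change in
   that correlation between normal tissue and tumors is evidence that the
   communication line itself is rewired, even when neither gene is
   differentially expressed.
2. **Single-cell data.** With cells grouped into annotated types, a directed
   communication edge `sender -> receiver` via pair (L, R) is called when L
   is highly expressed in the sender type and R in the receiver type. This
   covers autocrine edges (sender equals receiver) as well as paracrine
   ones.

Both proxies are correlational: they nominate candidate communication lines
for mechanistic follow-up, they do not demonstrate signaling.

# The pair database

`load_pairs()` reads a two-column (ligand, receptor) TSV into a `pair_db`.
The relation is deliberately *not* bijective: one ligand may bind several
receptors (the packaged 12-pair demo table contains both a shared-receptor
group and a multi-receptor ligand), and the container keeps the per-ligand
receptor groups explicit. At the scale of curated interactomes (~2,500
pairs over ~700 ligands and ~700 receptors) the space of *unordered random
gene pairs* is over three million (`count_unordered_pairs(2558)` =
3,270,403), which is what makes a random-pair null distribution
(`sample_random_pairs()`, `random_null()`) meaningful: the curated pairs
are a vanishingly small, biologically selected subset of that space.

# Bulk pipeline

## Differential expression with a moderated t

Expression is modeled gene-by-gene on the `log2(x + 1)` scale with an
ordinary least-squares two-group fit (`fit_linear_model()`); with
indicator coding the contrast coefficient is exactly the cancer-minus-normal
difference of group means. Per-gene residual variances from small cohorts
are noisy, so `moderate()` shrinks them toward a common prior: the posterior
variance is

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

and the t-statistic built on it has $d_0 + d$ degrees of freedom. The prior
$(d_0, s_0^2)$ is estimated by moment matching on
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, whose theoretical variance is
the trigamma function $\psi'(d_0/2)$ of the unknown prior degrees of
freedom; the trigamma equation is inverted by bisection (tolerance
`1e-8`), since trigamma is strictly decreasing and the root is bracketed by
construction. The two limits are useful checks and are exposed: `d0 = 0`
reproduces the ordinary t exactly, `d0 = Inf` uses the common variance for
every gene. The default `moderate()` estimate is cross-checked in the test
suite against the independent `limma` implementation of the same
empirical-Bayes model.

`select_de()` applies the conventional thresholds |log2 fold change| >= 1
(i.e. 2-fold, `fc_threshold = 2`) and p < 0.05 (`p_threshold = 0.05`),
with `use_fdr = TRUE` switching the cutoff to Benjamini-Hochberg adjusted
values. `classify_pairs()` then places every database pair into one of the
regulation scenarios (both up, both down, discordant, one-sided, none) — a
coarse but interpretable summary of how the two sides of each communication
line move.

## Per-pair correlation within condition

`pair_correlations()` computes, per ligand and per condition, the Spearman
correlation between the ligand and the **element-wise sum of its measured
receptors** on the linear scale. Summation is the package's rule for
non-bijective relations: the receiver side of a communication line is the
total cognate receptor pool, and summing (rather than averaging or taking
the maximum) keeps highly expressed receptors dominant while remaining
monotone in every component. Random pairs (`random_null()`) are *not*
summed — they are single gene-gene correlations — because the null is
"two arbitrary genes", not "an arbitrary ligand with an arbitrary receptor
group".

Spearman rather than Pearson: expression is heavy-tailed and the proxy only
claims monotone association, so rank correlation's invariance to monotone
transforms (log, normalization changes) is exactly the robustness wanted.
Distributions of coefficients are compared with the two-sample
Kolmogorov-Smirnov statistic (`ks_compare()`, asymptotic p-values), and
summarized by mean, SD and the coefficient of variation CV = SD/|mean|
(`summarize_distribution()`): a coherent, biologically constrained set of
pairs has CV well below a random set whose mean sits near zero.

## Correlation shifts and the noise band

`classify_shift()` places each pair on the (ρ_normal, ρ_cancer) plane:

* **Area I** — gained correlation in cancer: ρ_normal in (−0.25, 0.25) and
  ρ_cancer > 0.5;
* **Area II** — lost negative correlation: ρ_normal < −0.5 and ρ_cancer in
  (−0.25, 0.25);
* **Area III** — lost positive correlation: ρ_normal > 0.5 and ρ_cancer in
  (−0.25, 0.25).

The bands are open and the cuts strict, so the three areas are disjoint by
construction (the test suite asserts the partition on a 0.01 lattice of the
square). The gap between the "uncorrelated" band (±0.25) and the
"correlated" cut (±0.5) is deliberate: sample correlations of truly null
pairs at cohort sizes of 60–150 have a standard deviation of roughly
1/sqrt(n−3) (0.08–0.13), so a pair must move across a buffer several times
that noise scale before it changes category. `estimate_noise_band()` makes
this calibration explicit for a given cohort: it repeatedly splits the
normal samples into two random subsets (default two groups of 65, the scale
of a typical tumor-adjacent-normal cohort) and reports the 95th percentile
of |Δρ| across pairs and replicates — the shift magnitude that random
resampling alone can produce. All four cuts are user-configurable through
`shift_thresholds()`. `recurrence_rank()` aggregates shift tables across
cohorts and ranks pairs by the number of cohorts in which they land in the
same area (ties broken by mean |Δρ|, then lexicographically, so rankings
are deterministic).

## Infiltration stratification

Bulk tumor samples are mixtures; a correlation attributed to tumor cells may
be driven by infiltrating immune or stromal cells. `quantile_split()`
stratifies a cohort by an infiltration fraction (lymphocyte, monocyte,
neutrophil, stromal) into the lowest and highest quartiles (`q = 0.25`,
type-7 quantiles, boundary ties kept on both sides so the split never
depends on sample order). `compare_infiltration_groups()` then contrasts
the per-pair correlation distributions of the two strata with a 99-point
Q-Q grid and a K-S test. An association that survives in the low-infiltration
stratum is less likely to be an admixture artifact.

# Single-cell communication network

`call_high()` implements a mean-plus-k-sigma rule (`k = 3`): gene g is
"high" in type t when the type's mean expression exceeds a reference mean
plus k reference standard deviations. The reference matters more than it
seems:

* The default (`scope = "pooled"`) computes the reference mean and SD over
  all cells *excluding the type being tested* (leave-one-type-out). This is
  the statistically sound reading of "high relative to everything else":
  the tested type does not contaminate its own null.
* `scope = "pooled_all"` includes the tested type's cells in the reference.
  With T roughly equal-sized types, a single elevated type contributes its
  own signal to both the reference mean and (quadratically) the reference
  SD; writing f for the type's cell fraction, the standardized elevation is
  bounded near $(1-f)/\sqrt{f(1-f)}$ times less than the naive reading
  suggests, and at f = 1/7 a 3-sigma exceedance is out of reach no matter
  how strong the elevation. The option is retained because it is the
  obvious first implementation, and the package's tests demonstrate its
  blindness explicitly.
* `scope = "per_type"` standardizes each gene against the mean and SD of
  its T per-type means. This cannot work at all for k = 3 and T = 7: the
  largest standardized deviation among T numbers is analytically bounded by
  $(T-1)/\sqrt{T} \approx 2.27 < 3$, so the rule would never fire on any
  input. The variant exists to document the bound, which the test suite
  asserts on randomized inputs.

Genes with zero reference variance are never called high (a constant gene
carries no evidence of specificity). Calls are invariant under global
rescaling of the matrix, and lowering k can only add calls. Counts should be
depth-normalized first (`normalize_cells()`, counts-per-10k with an
optional log2 transform) when library sizes differ across types.

`build_network()` emits one directed edge per (sender, receiver, ligand,
receptor) combination with the ligand high in the sender and the receptor
high in the receiver — a directed multigraph, since two types may
communicate through many pairs, exportable with `export_graphml()`.
`exclusiveness()` scores how private a gene is to a type: its mean there
divided by the unweighted mean of the per-type means (1 = uniform, T =
perfectly exclusive in one of T types; the unweighted mean keeps the score
independent of type sizes). `rank_edges()` orders edges by the geometric
mean of the sender-ligand and receiver-receptor exclusiveness — an edge
must be specific on *both* sides to rank highly — and keeps the top 2% by
default (`top_fraction = 0.02`, at least one edge, ties broken
lexicographically).

# The synthetic-data generator

Real tumor cohorts cannot be shipped inside a package, so validation rests
on generators with *known planted truth* (`simulate_bulk()`,
`simulate_single_cells()`, `simulate_infiltration()`); every simulation
returns the truth record alongside the data.

**Bulk cohorts** draw genes independently from a log-normal marginal
(meanlog = log 100, sdlog = 0.5 — right-skewed, strictly positive, the
shape of normalized bulk expression; a negative-binomial marginal is
available for count-like data). Planted correlations use a Gaussian copula:
to hit a *Spearman* target ρ_s, the latent normal correlation is set to
$r = 2\sin(\pi \rho_s / 6)$ — the exact closed-form relation between a
bivariate normal's Pearson correlation and its Spearman correlation — and
the two uniforms are pushed through the marginal quantile functions.
Because Spearman is rank-based, it survives this transformation exactly, so
the calibration is analytic, not tuned; the acceptance tests verify bias
below 0.03 across targets from −0.6 to 0.8. Planted differential expression
multiplies one condition's scale by a fold change. Planted infiltration
associations re-pair the *observed* ligand and receptor values within an
infiltration stratum by the ranks of copula-correlated normals: marginal
value multisets are preserved exactly while the within-stratum rank
correlation is set to its target.

**Single cells** are negative-binomial (mu = 1, size = 2 by default —
sparse, overdispersed counts typical of droplet data). A planted edge
multiplies the ligand's mean in the sender type and the receptor's mean in
the receiver type by `elevation` (an elevation of 1 is a no-op, which is
the natural negative control).

What the generator does **not** emulate: gene-gene correlation beyond the
planted pairs (real co-expression networks are pervasive), compositional
coupling between infiltration and expression (fractions are independent
Beta(2, 5) draws unless an association is planted), batch effects,
zero-inflation beyond what negative-binomial sampling produces, and
sample-to-sample library-size variation in bulk. Null results on synthetic
data are therefore cleaner than they would be in tissue; the generator is a
correctness harness, not a tissue model.

# Reproducibility and numerics

All stochastic entry points take a mandatory `seed` and restore the global
RNG state afterwards, so simulations are reproducible and side-effect free.
`run_pipeline()` derives fixed offsets from a single configured seed,
writes every table deterministically, and records inputs, thresholds,
package version and outputs in `manifest.json`; reruns with the same
configuration produce byte-identical tables. Numerical conventions: type-7
quantiles (the R default) throughout; K-S p-values are asymptotic
(`exact = FALSE`) so tied ranks never error; Spearman on fewer than 3
points or on a constant vector is refused or returned as `NA` with a
warning rather than silently fabricated; BH adjustment uses
`stats::p.adjust`.

# Limitations

* Co-expression is an indirect proxy: ligand-receptor correlation can arise
  from shared regulation or composition without any signaling, and real
  signaling can occur without correlation (post-transcriptional control,
  spatial restriction).
* Bulk correlations mix cell-intrinsic and compositional signal; the
  infiltration stratification reduces but does not remove this.
* The high-expression rule is threshold-based; k = 3 with the
  leave-one-type-out reference is conservative by design, and weak but real
  communication lines below the threshold are missed.
* The shift areas discretize a continuous plane; pairs hovering near the
  cuts will flicker between categories across cohorts, which is why
  `estimate_noise_band()` and `recurrence_rank()` should be read together.
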