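---
title: "chd8net: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chd8net: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery: what
each stage assumes, which tunable parameters matter, how the synthetic world
is constructed, and where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# The scientific setting

CHD8 is a chromatin remodeller with the strongest de novo loss-of-function
association with autism spectrum disorder. The analysis chain implemented
here asks three connected questions: (1) are known ASD risk genes
over-represented among promoters bound by CHD8 across neurodevelopmental
contexts; (2) does knocking CHD8 down dysregulate precisely those targets;
and (3) does adding a binding indicator to a network-based risk model
(DAWN) improve risk-gene prediction, quantified by a covariate effect `d`
and its bootstrap test.

# Peak annotation

Coordinates are BED-convention throughout: 0-based, half-open. One-based
inputs must be converted at the reader boundary.

*Reproducible regions.* A region is supported when peaks from two biological
replicates overlap by at least one base; the merged coordinates of the
overlapping cluster are reported. The ≥ 1 bp threshold is fixed by
convention; `min_overlap` exists for exploration only. For multi-region
tissues, `group_reproducible()` applies the rule to every replicate pair
within a group (e.g. cortical vs non-cortical) and unions the groups —
union, not intersection, is the default because the merged tissue set should
contain any site reproducible in either compartment; both behaviours are
reachable through the grouping argument.

*Promoters.* The promoter of a gene is the union over isoform TSSs of
exactly 1,000 nt upstream, strand-aware. Two representations are stored:
per-isoform intervals (each ≤ 1,000 nt) and their merged union. Overlap
queries use the union; `promoter_size` counts unique promoter nucleotides,
which is the weight used by the promoter permutation. Peak classification has
total precedence promoter > exon > distal, so every peak receives exactly one
class; peaks on unknown chromosomes are distal with a warning rather than an
error, since cross-assembly strays are common in practice.

*Venn partition.* Each reproducible interval of each context is labelled
with the exact set of contexts it overlaps. "Cells are disjoint" is
implemented as membership disjointness — every input interval lands in
exactly one cell and the cells exhaust the inputs. Base-level disjointness
cannot hold in general (an interval may overlap a neighbour that itself
touches a third context), so it is not asserted.

# Permutation enrichment tests

Gene-level mutability is
\[ M = \sum_j (1.2754\,g_j + 0.7246\,(1-g_j))\, s_j\, c_j , \]
with GC fraction \(g\), exon size \(s\) (nt) and covered fraction \(c\) per
exon locus. The constants are the relative expected mutation rates of GC and
AT nucleotides. Coverage defaults to 1 when no coverage estimate is
supplied; the package never computes coverage from BAMs — it is an input.

Sampling without replacement follows the literal cumulative-weight-inversion
procedure with rejection of repeats. Rejection from the full cumulative
distribution is distributionally identical to renormalizing over the
remaining genes (successive sampling); the implementation draws rejected
batches vectorized, which changes the RNG stream but not the distribution.
Tests verify the implied set distribution against exact enumeration on small
universes.

The one-sided empirical p-value is the fraction of iterations whose null
overlap is at or above the observed one. With zero exceedances the result is
reported as `< 1/n_iter` (e.g. `< 0.0001` at the default 10,000 iterations);
the raw zero is also stored. Universes should be restricted upstream to
active promoters on the exome-capture list; the package treats that
restriction as the caller's responsibility because activity calls are an
input annotation.

Promoter-size weights are computed per gene independently; nucleotides shared
by the promoters of two genes are counted for both, since per-gene totals are
what the weighting is defined on.

# Co-expression networks

For each seed, all background genes are ranked by Pearson correlation across
samples; the top `k = 20` with \(|r| \ge 0.7\) become neighbours. Ranking
uses \(|r|\) and edges keep the sign — networks in this setting display both
positive and negative edges — with a `use_abs = FALSE` option for
positive-only analyses. Ties at rank k break by lexicographic gene
identifier, making networks a deterministic function of the inputs.
Zero-variance genes yield undefined correlations and are simply never
neighbours.

The seed-permutation test rebuilds the network from random seed sets of equal
size drawn uniformly from the background (seeds are permuted, not risk
labels, so no mutability weighting applies). Seeds — observed or permuted —
are excluded from hit counting, which removes the trivial contribution of a
seed that is itself in the query set.

# Knockdown differential expression

Filters run in a fixed order and each stage is reported: grand total ≤ 20;
all remaining counts from a single experimental unit; then, on
library-scale-normalized counts, maximum within-treatment variance-to-mean
ratio (VMR) > 100. VMR with group mean 0 is defined as 0, so an all-zero
group can never remove a gene. Under Poisson sampling the VMR of four draws
is near 1 (the acceptance script computes ≈ 0.997 over 100,000 replicates);
the threshold of 100 only removes genes far outside anything a negative
binomial with success rate 0.05 (VMR 20) would produce.

Library-scale normalization maps \(x_{ij} \mapsto x_{ij}\,\bar s/s_i\), so
every column sums to the mean library size. TMM factors are implemented
directly (weighted mean of log2 ratios to a reference column after trimming
30% of log-ratios and 5% of intensities per tail, inverse-variance weights,
geometric re-centring) because the trim fractions are part of the stated
procedure and the test-suite needs the pre-recentring factor; the edgeR
implementation serves as an independent oracle in the tests. Note one
convention: with library sizes taken from column sums, a column that is an
exact 2× copy of the reference has factor 1 — the doubling is a library-size
effect, not composition bias. The "factor 2" intuition applies when equal
library sizes are supplied explicitly, and `trimmed_mean_factors()` exposes
`lib_size` for exactly that reason.

Per-gene models are log-linear GLMs with batch and knockdown effects. The
offset is the log *effective* library size (library size × TMM factor) —
the stated phrase "offset set to log(x_ij)" is read as this standard
construction, since a per-observation offset of the response itself is not a
model. The knockdown coefficient is tested by likelihood ratio by default
(better calibrated than Wald at four replicates per arm; Wald available).
The Poisson model is the dispersion-0 special case; the negative-binomial
path estimates per-gene dispersions by method of moments within treatment
groups and shrinks them toward the global mean with weight 0.5 (tunable) —
the shrinkage target and weight are design choices, as the variance-shrinkage
step is otherwise unspecified. Strong dysregulation requires all three
printed criteria: \(p < 0.05/(n_\text{genes}\times 2)\), \(|\log_2 FC| >
0.1\), \(\log_2 CPM \in [2, 10]\).

# Gene-set statistics

The subset test is a two-sided Wilcoxon rank-sum on DE p-values of members
versus a disjoint background (active genes not bound, by default); exact
enumeration below 25 per side without ties, normal approximation with
continuity correction otherwise. Because it uses ranks only, any monotone
transform of the p-values leaves it invariant.

Set-level p-values grow more extreme with set size for a fixed effect, so
subsets of different sizes are compared through residuals from a smoothed
quadratic spline of p-value against size: a penalized quadratic B-spline on
equally spaced knots with a third-order difference penalty (global quadratics
live in the penalty null space, so exact quadratic data are reproduced with
zero residual at any smoothing level) and GCV over a λ grid. GCV degenerates
toward interpolation with few points, so candidates with effective df above
0.8 n are excluded — with the handful of subsets this analysis feeds in,
that guard is what makes the residuals meaningful. Fitting defaults to the
raw p scale; a `-log10` option exists because the residual sign convention
admits two readings (a dysregulated subset shows a *negative* residual on
the p scale but a *positive* one on the −log10 scale) — the package
computes either orientation and labels it, leaving the choice to the
analyst.

Pathways need ≥ 20 members among the tested genes (size counted after
intersection with the quality-filtered universe). The significance threshold
defaults to the Bonferroni correction for the number of pathways actually
tested across two constructs — 0.00011 for 218 pathways — rather than a
hard-coded constant; 0.001 flags "notable". Risk lists get two tests per
list (one per construct) at per-test level 0.05/2 = 0.025.

# Extended DAWN

Association p-values are converted one-sided, \(z = \Phi^{-1}(1-p)\), with
p clamped to \((10^{-12}, 1-10^{-12})\); under the null z is standard
normal.

*Network.* Lasso neighbourhood selection (Meinshausen–Bühlmann): each
standardized gene is regressed on all others; edges aggregate with the OR
rule by default (AND available). The penalty is chosen by the power-law
criterion: regress log degree-frequency on log degree (degrees ≥ 1) per
candidate λ and keep the λ with maximal R², ties to the sparser network.
Candidates with fewer than three distinct positive degrees cannot be scored;
if none can, the largest λ with a non-empty network is returned with a
warning. "Key node" focusing restricts the regressions to key genes plus
genes correlated with at least one of them above a cutoff — the stated
adjustments are not detailed, so this minimal, configurable version is the
package's reading.

*Model.* Hidden risk states follow the generalized Ising prior
\[ P(I) \propto \exp\!\big( b \textstyle\sum_i I_i + \eta \sum_{(i,j)\in E}
I_i I_j + d \sum_i H_i I_i \big), \]
with binding indicator H and \(d \ge 0\) under M1 (M0 fixes \(d = 0\));
z-scores are N(0,1) for non-risk and N(μ, σ²) for risk genes. Fitting
alternates (i) Gibbs imputation of I given the current parameters, (ii)
moment updates of (μ, σ) from the posterior weights, and (iii)
pseudo-likelihood updates of (b, η, d) — a weighted logistic Newton step on
the sampled configurations, aggregated over (neighbour-sum, H) cells. The
coupling or binding column is dropped from the Newton system whenever its
sampled sufficient statistic carries no variation (empty networks, collapsed
states), and negative d is clamped to 0 with a refit of the remaining
parameters. Initialization thresholds z at the null's top decile; r = 0.5 is
the initial risk proportion for prior simulation. Convergence is declared
when all parameter changes fall below 1e-4; because Gibbs noise rarely
drops below that, the 200-iteration cap is the practical stopping rule, and
the cap is part of the estimator's definition here. A posterior that
collapses to all-0 or all-1 is flagged degenerate and the last stable
iterate returned. Identifiability requires H to vary under M1; a constant H
raises an error directing the caller to M0.

*Bootstrap test for d.* Fit M0; repeatedly simulate I from the fitted null
prior by single-site Metropolis–Hastings (convergence monitored by the
running mean of ΣI over 25-sweep windows, relative tolerance 1e-3, capped
at 200 sweeps), draw z from the fitted mixture, refit M1, and record the
null d. The empirical p-value is the fraction of null d values at or above
the observed one; an observed d of 0 gives p = 1 by construction. The
"smoothed" element is the parametric simulation from the fitted null —
no extra kernel noise is added, matching the enumerated procedure. Bootstrap
refits warm-start at the observed M1 estimate with a reduced budget
(max 50 outer iterations, 30 burn-in sweeps, 10 retained samples, no final
posterior pass). Crucially, the observed comparison statistic is computed by
that *same* reduced-budget estimator: Monte-Carlo noise in the
pseudo-likelihood step is rectified by the d ≥ 0 clamp, so a low-budget
estimator has a higher d under the null than a high-budget one, and mixing
budgets between the observed and simulated sides makes the test badly
conservative (we measured roughly 0.005 empirical size at nominal 0.05
before matching; the acceptance suite verifies the matched test sits inside
the binomial confidence band around 0.05). The full-budget M1 fit is still
returned for parameter reporting.

*Risk calls.* Genes ranked by posterior; the q-value at rank k is the
running mean of (1 − posterior) over the top k, and the largest prefix with
q ≤ 0.05 is flagged (Bayesian FDR). Ties in the posterior break by gene
identifier.

# The synthetic world

`sim_config()` fixes one stated world; its defaults are chosen once and are
not tuned against test outcomes:

* 2,000 genes on 4 toy chromosomes; 1–10 exons per gene with
  \(g \sim \mathrm{Beta}(5,5)\), sizes log-normal around 150 nt,
  \(c \sim \mathrm{Beta}(20,2)\); 70% of promoters active — mirroring the
  scale of exon counts and the high-coverage regime of exome data.
* Three binding contexts (two human, one mouse) binding 25% of genes each;
  60% of each context's targets form the conserved core and the two human
  contexts share a further 15% tranche — a graded overlap structure of the
  kind real multi-tissue binding maps show, which is what gives the
  spline-residual analysis a dilution gradient to detect.
* A 120-gene risk list drawn with odds multiplier 8 for core-bound genes —
  near the observed ratio of bound risk genes to expectation.
* Counts: 3 arms (control plus two knockdown constructs) × 4 replicates in
  2 batches; negative-binomial counts parameterized by success rate 0.05
  (constant VMR 20 at any mean — the description the VMR screen was designed
  around; a mean-dependent-dispersion parameterization would let the screen
  remove ordinary high-expression genes, which is not the stated behaviour);
  log-normal baselines around 200 counts, batch effects of 0.1 log-sd,
  library sizes 0.2 log-sd; knockdown effects of |log2FC| ≈ 0.4–0.75 on 30%
  of core-bound genes, 80% of them down-regulated; planted violators of each
  QC rule under `qc_*` identifiers.
* Co-expression: 25-gene blocks at pairwise correlation 0.9 around each
  seed, 30 samples — enough to saturate the k = 20 neighbourhood of every
  seed.
* Risk field: scale-free graph (preferential attachment, m = 2), Ising
  parameters (b = −2, η = 0.5, d = 1.5, μ = 2, σ = 1) — the
  parameter-recovery configuration.

Every generator is a pure function of (config, seed); `simulate_world()`
derives per-stage seeds from the master seed. What the world does *not*
emulate: real genome sequence, read-level noise, mappability artefacts,
correlated mutability between binding and risk (available as an option but
off by default), isoform-level expression, or the actual consortium data —
so a green end-to-end test establishes internal consistency of the methods
on data satisfying their assumptions, not reproduction of any published
gene list.

# Scaling choices in the tests

The acceptance suite runs at desk scale on one CPU: the type-I-error check
of the bootstrap test uses 150-gene fields (200 repetitions × 200 bootstrap
rounds as stated), parameter recovery uses 500 genes × 20 replicates, and
the end-to-end world uses 1,200 genes. These sizes are scale reductions,
not parameter changes: all model constants, thresholds and rates are the
stated ones.

# Known limitations

* Pseudo-likelihood (not exact likelihood) estimation of the Ising
  parameters; with strong coupling the estimates are attenuated relative to
  the exact MLE, and `d` estimates on estimated (rather than true) networks
  inherit that attenuation.
* The Monte-Carlo convergence tolerance means `fit_hmrf()` effectively runs
  to its iteration cap; results are exactly reproducible given a seed but
  carry sampling noise of order the Gibbs standard error.
* GCV spline smoothing with fewer than ~6 points depends on the 0.8 n
  effective-df guard; with exactly 4 points the fit is close to a plain
  quadratic regression.
* The trimmed-mean reference column follows the upper-quartile heuristic;
  data where most genes are zero in some unit can make that choice unstable
  (as with any TMM implementation).
* `seed_permutation_enrichment()` recomputes a full correlation matrix per
  permutation; at 10,000 iterations on large backgrounds this is the
  pipeline's slowest step and is best run with a restricted background.
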