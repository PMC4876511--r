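---
title: "Methods: pool-seq FST and environmental association along altitudinal gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq FST and environmental association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

`altigrad` implements an inference chain for detecting environment-associated
genetic differentiation among populations sequenced as pools (pool-seq).
The setting it targets is a set of plant populations sampled along a steep
altitudinal gradient: RNA from ~100 individuals per site is pooled and
sequenced, so allele frequencies must be estimated from read counts rather
than genotypes, and expression differences between sites contaminate
coverage. The chain is:

1. **Variant filtering** to the calling rules of the study design: pooled
   minor-allele frequency >= 0.05, coverage >= 20 in every pool, removal of
   positions absent from all pools.
2. **Coverage equalisation**: exclusion of the upper 2% most highly covered
   positions (expression tail), then replicated random sub-sampling of reads
   to an even target coverage (10 per pool for single datasets, 20 for
   combined ones), averaging the alternate-allele fraction over 50
   replicates.
3. **Pool FST**: per-SNP heterozygosity components with a finite-pool
   correction, aggregated to gene-level FST as a ratio of sums; Fisher's
   exact tests on the sub-sampled counts give per-gene significance, and
   genes with at least one population pair at `-log10 p >= 1.301` are the
   "highly variable" screen set.
4. **Population structure**: a genome-wide pairwise FST matrix, and a
   majority-rule consensus of 500 neighbour-joining trees built from
   locus-bootstrapped FST matrices.
5. **Environmental association**: partial Mantel correlation of each gene's
   pairwise FST matrix with each retained bio-climatic factor's distance
   matrix, controlling for the genome-wide FST matrix; a simulation-derived
   95%-quantile effect-size threshold; and a three-step stringency filter
   (threshold, permutation significance, stress-related GO annotation).
6. **GO over-representation** of candidates by one-sided Fisher tests with
   Benjamini-Yekutieli FDR control.

Every stage is exercised end-to-end on synthetic data with planted truth, so
the package's tests measure recovery of known signal rather than agreement
with any particular empirical dataset.

# The FST estimator

For one SNP and pools $i \in \{1,2\}$ with alternate frequencies $p_i$ and
effective sizes $n_i = \min(\text{haploid pool size}, \text{coverage})$:

$$\pi_i = 2 p_i (1 - p_i)\frac{n_i}{n_i - 1}, \qquad
\pi_S = \tfrac{1}{2}(\pi_1 + \pi_2),$$
$$\bar p = \tfrac{1}{2}(p_1 + p_2), \qquad
\pi_T = 2 \bar p (1 - \bar p)\frac{\tilde n}{\tilde n - 1},
\quad \tilde n = \min(n_1, n_2),$$
$$F_{ST} = \frac{\pi_T - \pi_S}{\pi_T},$$

clamped at 0 and undefined when $\pi_T = 0$ (both pools fixed for the same
allele). This is the classical pool-seq heterozygosity estimator with the
$n/(n-1)$ unbiasedness correction; the Karlsson-style alternative is out of
scope. Gene-level FST is the **ratio of sums** $(\sum\pi_T - \sum\pi_S)/\sum\pi_T$
over the gene's defined SNPs, the windowed-tool convention; raw components
are summed without per-SNP clamping so the ratio stays unbiased, and only
the final ratio is clamped. A mean-of-ratios variant is available behind the
`mean_of_ratios` flag for sensitivity checks. The genome-wide matrix $D^s$
uses the same ratio of sums over all SNPs; it replaces a genotype-based
estimator, which pooled data cannot support.

Fisher's exact tests use the rounded sub-sampled counts at target coverage
(round-half-to-even), since testing happens after the synchronized dataset is
built. The per-gene statistic is the mean of $-\log_{10} p$ over the gene's
SNPs (the windowed-tool behaviour); an "at least one significant SNP" rule is
available behind `any_snp_significant` because the underlying convention is
ambiguous. The two-sided p-value is computed by exhaustive hypergeometric
enumeration with the conventional $1 + 10^{-7}$ relative tolerance; a lookup
table over all $(t+1)^2$ tables at target coverage $t$ makes genome-scale
testing cheap.

# Partial Mantel screen and thresholds

For gene matrix $D^x$, factor matrix $D^y_{ij} = |y_i - y_j|$ and control
$D^s$, the statistic is the first-order partial Pearson correlation of the
unfolded upper triangles:

$$r = \frac{r_{xy} - r_{xs} r_{ys}}
{\sqrt{(1 - r_{xs}^2)(1 - r_{ys}^2)}}.$$

Significance is one-sided (positive association), by jointly permuting the
row/column labels of $D^x$. With $n \le 5$ sites only $n!$ distinct
relabellings exist, so the permutation distribution is enumerated
exhaustively (identity included, $p = \#\{r_\pi \ge r_{obs}\}/n!$); 1000
random label permutations of a 4x4 matrix would repeatedly sample 24 points.
For larger $n$, $p = (\#\{r_\pi \ge r_{obs}\} + 1)/(m + 1)$ over $m$ sampled
permutations. Permutations are shared across factors within a gene (it is
$D^x$ that is permuted) and each gene uses a deterministic sub-stream of the
root seed.

The effect-size threshold $r^*$ per factor is the 95% empirical quantile
(linear interpolation) of the **signed** partial $r$ over simulated gene
matrices whose upper-triangle entries are i.i.d. Uniform(0,1) — no metric or
triangle constraint, deliberately mirroring how such null matrices are
declared ("FST values between 0 and 1 randomly generated"). Signed rather
than absolute $r$ is used for both threshold and screening because the
screen targets positive association and published cut-offs of this design
are one-sided values near +0.8. The number of simulated matrices
conventionally matches the number of screened genes.

The three-step filter keeps gene-factor results with (1) $r > r^*$ strictly,
(2) permutation $p \le 0.05$, and (3) the gene annotated with
`response to abiotic stimulus` in an ancestor-closed annotation table. GO
membership is a flat lookup; no DAG reasoning is performed beyond the
ancestor closure of the input.

A calibration subtlety, verified empirically in the tests: the step-1 pass
fraction equals $1 - q$ (here 5%) *by construction* only for genes whose
matrices are exchangeable with the simulation null. Drift-generated gene
matrices have structured dependence between pairs sharing a pool, and their
pass rate is mildly inflated (about 6% at 8 pools, and substantially more at
4 pools where only 6 distance pairs exist). The acceptance checks therefore
assert the binomial band on independent draws from the simulation null, and
check permutation-p uniformity on drift-generated null genes, where it does
hold.

# Trees

Neighbour joining follows Saitou-Nei via `ape::nj`; negative branch lengths,
which NJ produces on noisy matrices, are floored at zero with the deficit
moved to the sibling edge so path lengths through the parent are preserved.
The consensus tree resamples **loci** (SNP components) with replacement,
recomputing the genome-wide FST matrix per replicate; resampling matrix
cells instead was rejected because it destroys the metric structure the tree
is built from. Majority-rule (> 50%) consensus node labels give the
percentage of 500 replicate trees containing each bipartition.

# Climate preparation

Growing-season variables (MTGS, MPGS, MRGS) are arithmetic means of the
monthly temperature/precipitation/radiation series over each site's
growing-season months. Pruning scans variables in a fixed order and drops
any with $|r| \ge 0.8$ against an already-kept variable; near-constant
variables (relative range below 0.2) are flagged and excluded — the
radiation-seasonality case, where a variable spanning only 0.19–0.22 across
sites carries no usable contrast. The scan order places growing-season
factors before their annual analogues, and MRGS before MPGS, so the
gradient-defining radiation factor survives pruning when a chance
wetness-altitude correlation (small-n site samples) links precipitation to
radiation. PCoA on the standardized retained variables (Euclidean distances,
Gower double-centring via classical MDS) summarises climatic separation of
the sites; raw values are used for the univariate $D^y$ matrices because
those are single-factor distances.

# The synthetic-data generator

The generator defines the study conditions; it is not a tuning dial. Its
defaults emulate the targeted design: 4 pools (configurable >= 4) of 100
diploids (ploidy 200) at altitudes 700/2000/2600/3400 m.

* **Ancestral frequencies**: mixture $0.5\,\mathrm{Beta}(20,1) +
  0.5\,\mathrm{Uniform}$, giving a high-fixation regime plus a uniform
  background, qualitatively matching the large fixed fraction seen in pooled
  transcriptome callsets.
* **Drift**: Balding-Nichols steps along a rooted tree whose branch lengths
  are $F$ parameters; child frequency $\sim$ Beta with mean equal to the
  parent frequency and variance $F p (1-p)$. The default four-pool tree has
  a near-identical terminal pair (P3, P4; $F = 0.005$ each) and a distal P1,
  the recoverable topology the structure stage is tested against.
* **Environmental link**: for planted genes, per-pool frequency is
  $\mathrm{logit}^{-1}(a + b z)$ with $z$ the standardized driving variable
  (growing-season radiation by default) and $b$ the single effect-size knob
  (default 3); $a \sim N(0, 0.7)$ per SNP.
* **Coverage**: negative binomial per SNP x pool with a per-gene expression
  factor; mean 80 and size 5 by default, so the >= 20-in-every-pool rule
  removes a modest fraction of positions as in deep pooled RNA-seq, while a
  2% heavy-tail gene set (5-12x inflated) exercises the upper-2% exclusion.
* **Population-private SNPs**: a configurable fraction (default 8%) of
  non-associated SNPs have true frequency zero outside one focal pool and
  Beta(2,2) within it, so private variants sit at lower frequencies than
  shared ones — the pattern the classification stage asserts.
* **Labels**: effect classes with probabilities (synonymous 0.45,
  deleterious non-synonymous 0.07, non-deleterious non-synonymous 0.38,
  unannotated 0.10), mirroring the observed composition of such callsets
  (~15% deleterious among non-synonymous); known-variant flags at 0.85;
  transitions drawn at rate 1.37/2.37 so the expected Ts/Tv ratio is ~1.37.
* **Climate**: monthly series with an altitude lapse in temperature, a
  monsoon precipitation peak scaled by site-random wetness, and radiation
  strictly increasing with altitude; a three-month growing season starting
  later at higher altitude; built-in highly correlated pairs (TS/TAR) and a
  near-constant RS to exercise pruning.
* **RNG contract**: one root seed; per-gene sub-streams derived
  deterministically, so growing `n_genes` never reshuffles earlier genes.

What the generator does **not** emulate: read-level errors and mapping bias,
linkage within genes (SNP frequencies are drawn independently given gene
effects), transcript models, migration after divergence, and real
bio-climatic covariance structure. Passing tests therefore demonstrate that
the chain recovers planted signal under its own stated model, not that any
empirical dataset would yield particular values.

# Numerical conventions

* Nearest-rank quantile for the upper-coverage exclusion (deterministic, no
  interpolation ambiguity); a position is dropped when over-quantile in
  *any* pool.
* Sub-sampling with replacement of $t$ reads from observed counts is
  binomial$(t, \hat p)$ sampling, implemented as such.
* Biallelic reduction: the alternate allele is the highest-count
  non-reference base summed over pools, ties broken in the fixed order
  A < T < C < G.
* "Fixed" means alternate count equals coverage in raw, pre-sub-sampling
  counts, avoiding sub-sampling artefacts in fixation statistics.
* Gene SNP density is measured as gene length per SNP (bp), binned
  left-closed with width 100.
* FST histograms use left-closed 0.01 bins with the final bin right-closed
  so a value of exactly 1 is counted.
* Empty subsets yield `NA` summaries, never 0; undefined FST components are
  excluded from aggregation rather than zeroed.
* Permutation p-values use the $(k+1)/(m+1)$ convention for sampled
  permutations and exact enumeration for $n \le 5$.

# Problem sizes in the test-suite scenarios

The parameter-recovery scenario uses 8 pools, 2000 genes, 50 planted
environment-associated genes with effect size 3; null calibration uses 8
pools and ~900 drifted genes plus 2500 simulation-null draws; tree recovery
uses the default 4-pool design with 400 genes and 500 bootstrap replicates.
These sizes give stable Monte-Carlo behaviour for the asserted bounds
(sensitivity >= 0.6, false-candidate rate <= 0.02, planted-pair support
>= 95%) while keeping the suite fast; all are the package's own choices.

# Known limitations

* The FST estimator is the classical heterozygosity ratio; no
  Weir-Cockerham or model-based pool-seq estimators.
* The association screen controls for overall structure only through the
  single $D^s$ matrix; no spatial autocorrelation modelling.
* With 4 sites the permutation test bottoms out at $p = 1/24$, so the
  $p \le 0.05$ step is exactly the "strict maximum over relabellings" rule;
  power at 4 sites is intrinsically limited.
* GO enrichment results depend on the chosen universe (default: all genes
  with at least one SNP); no term-level semantic clustering is performed.
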