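---
title: "Cross-platform correlation networks with micnet: models, parameters, and design choices"
author: "micnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform correlation networks with micnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micnet)
```

## The analysis micnet implements

Germ cell tumors are profiled on several unrelated platforms at once:
promoter methylation on a cancer-gene CpG panel (beta values in [0, 1]),
genome-wide miRNA abundance as hybridization counts, an embryonic-stem-cell
qPCR panel (Ct cycles), a handful of risk SNPs, and clinical phenotype
(age, sex, tumor location, histology). No single platform explains tumor
behavior; the interesting biology sits in the *correlations across*
platforms — a miRNA cluster that tracks a stem-cell gene, a methylation
locus that tracks histologic severity.

micnet implements that integration as a pipeline of small, testable stages:

1. **Per-platform preparation.** Methylation loci are dropped when their
   detection p-value exceeds 0.05 in at least 25% of samples (inclusive
   boundary) or when they are X-linked — the X chromosome is removed because
   a mixed-sex cohort makes X methylation a sex readout, not a tumor
   readout. Counts are normalized by the positive-control geometric-mean
   factor per lane, then floored at the 75th percentile of the
   negative-control counts. qPCR Ct values become delta-Ct against the mean
   of the housekeeping genes.
2. **Differential analysis.** A negative-binomial exact test on counts with
   Benjamini-Hochberg correction; `2^-ddCt` fold changes with the 3-fold
   flag (`|log2 fold| > 1.58`); Welch tests on delta-Ct; city-block /
   average-linkage clustering of samples.
3. **Fusion.** All platforms plus numerically encoded genotypes and
   phenotypes are stacked into one feature-by-sample matrix over the
   complete-data sample intersection.
4. **Association.** Every unordered row pair gets two dependence measures:
   the Pearson correlation (linear) and the Maximal Information Coefficient
   (MIC; any functional shape).
5. **Network.** Pairs are kept when they span two different platforms and
   either `|r|` or MIC reaches 0.75; connected components of that edge set
   (equivalently: single-linkage groups at the threshold) are the networks,
   and nodes with at least 4 neighbors are hubs.
6. **Enrichment control.** The hub-plus-neighbor gene list is tested for
   upstream-regulator over-representation (hypergeometric upper tail,
   BH-corrected) against a user-supplied GMT annotation, and every call must
   beat the minimum p-value obtained by three random gene lists of the same
   size drawn from the same profiled molecules — guarding against the a
   priori cancer/stem-cell bias of the panels.

## The MIC estimator

For a pair of vectors of length $n$, draw a $k \times l$ grid on the two
axes, compute the mutual information $I$ of the induced two-way table, and
normalize by $\log_2 \min(k, l)$ so a perfect functional relationship scores
1 on any grid. The MIC is the maximum of that normalized score over all
grids with $k \cdot l \le B(n)$ cells, $B(n) = \max(4, \lfloor n^\alpha
\rfloor)$.

Searching all grids is exponential, so micnet uses the standard two-step
approximation: one axis is *mass-equipartitioned* into $q$ rows (tied values
never split), and the other axis is then optimized exactly by dynamic
programming over *clumps* — maximal runs of consecutive points lying in one
row, which provably contain the optimal cut points. The number of candidate
boundaries is capped at `clump_factor * max_columns` by merging adjacent
clumps. Both axis orientations are searched and the larger value returned,
so `micApprox(x, y)` equals `micApprox(y, x)` exactly.

Two properties of this scheme matter for verification:

* the DP is exact for the optimized axis, so the only approximation is the
  equipartition of the other axis;
* the search space is a subset of all grids, so the approximation is a
  **lower bound** of the exact MIC.

`micExactOracle()` is a genuinely independent check: it enumerates *every*
admissible cut set on both axes (feasible for $n \le 12$) and takes the true
maximum. Below `exhaustive_small_n` (default 12) observations, `micApprox()`
switches to an exhaustive row-axis search as well, which makes the estimate
exact under the grid budget; the package's test suite verifies both the
exactness at small $n$ and the lower-bound property. The equipartition
heuristic at larger $n$ is the estimator actually used on 40-sample cohorts.

Parameters, all in `micParams()`:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.6 | grid budget exponent, $B(n) = \max(4, \lfloor n^\alpha\rfloor)$ |
| `clump_factor` | 15 | boundary cap multiplier for the DP |
| `min_pairwise_n` | 8 | below this many complete pairs the MIC is reported missing |
| `small_n_warning_threshold` | 30 | MIC inflates on small samples; warn below this |
| `exhaustive_small_n` | 12 | exact row-axis search at or below this n |

The 0.6 / 15 defaults are the canonical defaults of the MINE family of
estimators. MIC is known to report spurious dependence on very small
samples; at $n = 40$ the null distribution of MIC sits around 0.3–0.45,
which is why the network threshold of 0.75 (and 0.95 for null checks) is
comfortably above it, and why pairs with fewer than 8 complete observations
are not scored at all.

## The negative-binomial exact test

Counts for a feature are modeled as NB with a common mean per sample and a
per-feature dispersion $\varphi$ (variance $\mu + \varphi\mu^2$). The two
group sums are then NB as well (size $n_g/\varphi$, mean $n_g \mu$), and the
test conditions on the observed total $S$: the two-sided p-value is the
probability of all splits $(a, S - a)$ whose probability does not exceed the
observed split's, normalized by the total probability over splits.

The dispersion is estimated per feature by maximum likelihood over *all*
samples with the mean held at the sample mean — blind to the group labels.
This choice is deliberate: with 3–4 samples per group, a within-group
method-of-moments estimate is so noisy that its downward errors make the
exact test anticonservative (empirically a doubled type-I rate), while the
blind fit keeps the rejection rate at the 5% level within [0.04, 0.07]
across simulation seeds at the cost of extra conservatism for strongly
shifted features (their between-group difference inflates the blind
dispersion). With 8-fold planted shifts the test still reaches essentially
full power in the package's simulations, so the trade is cheap. No
cross-feature shrinkage or mean-dispersion trend is fit — with an 800-probe
panel and a conditional exact test, per-feature estimation keeps the
procedure simple and auditable. One consequence worth knowing: the p-value
distribution under the null is near-uniform in the rejection region
(no anticonservatism below $\alpha = 0.1$) but mildly distorted in the
mid-range, which is irrelevant for testing but visible in a QQ plot.

Normalized counts are reals after the positive-control scaling; the test
requires integers, so the pipeline rounds to the nearest integer at the
test boundary (documented, and asserted by the input validation).

## Encodings

Genotype calls are encoded with the transition/transversion grouping:
t/t = -4, c/t = -3, c/c = -2, g/t = -0.5, c/g = -0.2, a/t = 0.2, a/c = 0.5,
a/a = 2, a/g = 3, g/g = 4; the lookup is case- and order-insensitive
(`g/a` is `a/g`). Phenotypes get one numeric row each: age passes through;
sex is male = 0, female = 1; location ovary = 0, testis = 1,
extragonadal = 2; histology is ordered by severity normal_adjacent = 0,
teratoma = 1, dysgerminoma = 2, yst = 3, mixed = 4. **The phenotype codes
are package defaults stated as assumptions** — the severity ordering of a
mixed tumor relative to a yolk sac tumor is a judgment call — and every map
is overridable through `defaultEncodingConfig()`.

## The synthetic cohort generator

No cohort data are deposited for this kind of analysis, so the generator is
a first-class module: it produces data with the structure the pipeline
assumes, plus a truth record of what was planted, so every downstream claim
is testable.

The default cohort is 40 samples in five histology classes (8 yolk sac
tumor, 17 teratoma, 8 dysgerminoma, 3 mixed, 4 normal-adjacent — the
complete-data design, chosen so that excluding yolk sac tumors leaves 32
samples), with:

* 1505 CpG loci as logit-normal beta values; exactly 16 loci fail detection
  (p > 0.05 in 30% of samples, above the 25% removal fraction) and a
  disjoint set of exactly 84 loci is X-flagged, so QC retains exactly 1405;
* 800 miRNAs as negative-binomial counts, gene dispersions log-uniform on
  [0.05, 0.5], means log-normal, a per-sample lane factor, a 6-step
  positive-control geometric ladder scaled by the same lane factor (so
  positive-control normalization has something to remove), and
  Poisson(2) negative controls;
* an 84-gene Ct panel with 5 housekeeping genes and a per-sample plate
  shift (removed by delta-Ct);
* 4 SNPs drawn from Hardy-Weinberg equilibrium at allele frequency 0.3
  (the neutral default in the absence of published frequencies);
* annotations with histology-dependent age ranges and sex/location
  frequencies shaped like a germ-cell-tumor case series (dysgerminomas all
  female and ovarian, etc.).

**Planted structure.** Each `hubSpec()` introduces one latent variable per
sample — the numeric histology code plus noise for histology-driven hubs, a
standard normal otherwise. The hub feature loads on the latent with small
noise (a quarter of `noise_sd`); each spoke is `effect_size * f(latent)`
plus independent noise of sd `noise_sd`, with `f` the identity, a centered
square, or a sinusoid. Features are embedded on their platform's natural
scale: a gentle slope on the logit scale for beta values (keeping them in
the near-linear band of the logistic), a log-linear shift of the NB mean
for counts (for which the NB sampling noise itself plays the spoke-noise
role), and cycles for Ct. The default plants one linear 6-spoke hub on the
qPCR platform with 3 methylation and 3 miRNA spokes at
`effect_size = 2 * noise_sd`, which calibrates to hub-spoke |r| above 0.75
on the normalized scale in well over 90% of seeds.

Because all spokes share one latent, spoke-spoke correlations equal the
product of their hub-spoke correlations — at the default effect size, often
above the 0.75 threshold too. Planted "hubs" therefore recover as a clique
around the hub rather than a clean star, and spokes (and the histology row
that drives the latent) can legitimately satisfy the 4-neighbor hub rule.
The tests assert what the generative model actually implies: the planted hub
is recovered, and every recovered hub is a planted feature or a phenotype
driver, never an independent noise feature.

**What the generator does not emulate:** batch effects between arrays,
probe cross-hybridization, mixed-histology composition within a tumor,
realistic genomic coordinates, or missingness that is informative rather
than by-design. Passing the simulation suites therefore shows the pipeline
is correct and calibrated under its stated model, not that the model captures
every artifact of real array data.

## Numerical choices

* Beta values are the plain ratio M/(M+U); the array software's customary
  +100 denominator offset is available (`offset`) but off, because the
  two-term ratio is the definition the analysis states. M = U = 0 yields a
  missing value with a warning.
* "Upper quantile" background normalization is implemented as a per-sample
  **floor** at the type-7 (linearly interpolated) 75th percentile of the
  negative controls, not a subtraction: flooring keeps counts nonnegative,
  which the NB test requires. The quantile is configurable.
* The detection-failure boundary is inclusive (a locus failing in exactly
  25% of samples is removed).
* The 3-fold flag fires strictly above `|log2 fold| = 1.58` (so 1.58 itself
  does not pass; a true 3-fold change, log2 fold 1.585, does).
* Pearson qualification in the edge filter uses `|r|` by default — an
  anti-correlated cross-platform pair is biologically meaningful — with a
  flag for signed behavior.
* Hierarchical clustering delegates to `dist()`/`hclust()` (pairwise-complete
  city-block distances with proportional rescaling, average linkage);
  heights are nondecreasing for this metric/linkage pair.
* Ties everywhere break toward the lowest index (stable sorts in the MIC
  machinery; `hclust`'s deterministic agglomeration), so reruns are
  bit-identical.
* All simulation loops in the tests and in the acceptance checks run the
  generator at a reduced panel (60 CpG loci, 40 miRNAs, 20 qPCR genes,
  same 40-sample design; `smallCohortSpec()`), which keeps an all-pairs MIC
  scan near 7,000 pairs per seed. The full 1505-locus default is exercised
  where only generation and QC are needed.

## Known limitations

* MIC on 40 samples is a screening statistic, not a test; no p-values are
  attached to MIC and the threshold plays that role. Null-simulation checks
  use a raised threshold (0.95) precisely because small-sample MIC inflates.
* The NB test's blind dispersion trades power for calibration; with group
  sizes above ~8 a within-group estimator would be preferable.
* The fused matrix mixes scales (beta in [0, 1], counts in the thousands,
  Ct cycles, codes in [-4, 4]); both Pearson and MIC are
  location-scale-free per pair, so no global standardization is applied,
  but the optional `log2_mirna` fusion tames count skew if wanted.
* The enrichment stage is as good as the supplied GMT; the package ships no
  curated regulator knowledge base.
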