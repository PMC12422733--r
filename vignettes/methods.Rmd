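---
title: "Methods: cross-species TE/KRAB-ZNF co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species TE/KRAB-ZNF co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecnet)
```

This vignette documents the statistical choices behind `tecnet`: the
models, the defaults and why they were set where they are, what the
synthetic-data generator does and does not emulate, and the behavior of
each component on degenerate input.

## Cross-species scaling

### Model

Comparing TE-subfamily or gene expression between species requires a
species-level scaling factor: even after accounting for feature length
and sequencing depth, the compared feature set can sit at a different
overall scale in the two libraries (annotation coverage, rRNA content,
mappability, and genuine global expression shifts all contribute). For a
conserved feature with summed counts $x_A$, $x_B$, total library sizes
$N_A$, $N_B$ and lengths $L_A$, $L_B$, equal underlying expression under a
candidate factor $f$ implies that $x_B$ is binomial in $x_A + x_B$ trials
with success probability

$$p(f) = \frac{f N_B L_B}{N_A L_A + f N_B L_B}.$$

`estimate_scaling_factor()` tests every conserved feature with a
two-sided exact binomial test at level $\alpha$ and records the fraction
rejected (the empirical type I error) for each grid point; the selected
factor minimizes the absolute deviation between that fraction and
$\alpha$.

Counts are summed across replicate samples before testing because the
factor is a species-level constant; library sizes are matrix totals, so
no external normalization is assumed.

### Numerical choices

* **Grid.** 401 log2-spaced points spanning $2^{\pm 2}$ around the median
  moment estimate $\mathrm{med}\!\left(\frac{x_B}{x_A}\cdot
  \frac{N_A L_A}{N_B L_B}\right)$: a 16-fold range with < 0.7% spacing,
  wide enough that the optimum is interior in every simulation we run.
* **Exact test.** The two-sided p-value uses the minimum-likelihood tail
  definition of `binom.test`, recomputed with a binary search over each
  monotone flank of the mass function so that a full grid evaluation
  (~200,000 exact tests for 500 features) costs seconds. The suite checks
  agreement with `binom.test` to 12 digits.
* **Ties** in the objective break toward the grid point nearest 1 on the
  log2 scale — a no-change prior that is symmetric for reciprocal factors.
* **Degenerate input.** If species B is an exact copy of species A, every
  test at $f = 1$ has p-value ~1, the empirical type I error at 1 is
  exactly 0, and a slightly off-1 factor at which about $\alpha$ of the
  features reject attains a smaller deviation. The estimator therefore
  returns ~1 only up to grid resolution on *noisy* equal-expression data;
  on literally duplicated counts the deviation objective itself prefers a
  nearby factor. This is a property of the published objective, not of the
  implementation, and is why the tests exercise identity and doubling with
  resampled Poisson counts.
* **Overdispersion.** On negative-binomial counts the binomial equality
  test is anticonservative at the true factor (species-level sums have
  Fano factors far above 1), so the minimized deviation can stay well
  above $\alpha$. The rejection curve is still minimized near the true
  factor, which is what the estimator uses; calibration in the strict
  sense (type I error within two binomial standard errors of $\alpha$)
  holds for Poisson-level noise and is asserted there.
* **Confidence filter.** Only high-confidence ortholog rows enter the
  conserved set by default (`confidence = "high"`); the TE conserved set
  is restricted to subfamilies of the LTR, LINE, SINE, SVA and DNA
  superfamilies present in both species, with consensus lengths used on
  both sides.

## Differential expression

A deliberately compact negative-binomial Wald test: median-of-ratios size
factors, method-of-moments dispersion from the pooled within-group
variance (floored at $10^{-8}$), 50% shrinkage on the log scale toward a
log-linear mean–dispersion trend, and a Wald test of the log2 fold change
with a 0.5 pseudo-count added to both group means whenever either is zero
(this keeps the statistic finite and exactly antisymmetric under group
swap). BH adjustment is per contrast, not pooled across contrasts. The
default call threshold is $|\log_2 FC| \ge 1.5$ at adjusted $p < 0.05$;
condition contrasts within one species use 0.5 because expression
differences between conditions are much smaller than between species.
This estimator intentionally trades the refinements of the large DE
frameworks (shrunken fold changes, covariates, outlier handling) for a
dependency-free, fully testable core; it is validated on planted
fold-change simulations and for type I error control, and bit-level
agreement with any particular external DE package is not a goal.

## Correlation layer

All-pairs Pearson correlation between a gene set and a TE set within one
sample group; p-values from the exact t transform with $n-2$ degrees of
freedom ($|r| = 1$ reports p = 0, not machine epsilon); BH correction
jointly across **all** pairs of the group (positives and negatives in one
family, one family per group) because a single adjusted-p threshold per
group is what the downstream thresholds assume. Significance =
$|r| > 0.4$ and adjusted $p < 0.01$.

Supporting rules:

* **Presence filter** (default: count > 0 in ≥ 80% of the group's
  samples) defines "expressed" features. Published descriptions of such
  studies rarely pin this down; 80% keeps features quantified in nearly
  all samples while tolerating a dropout, and it is exposed as
  `presence_frac` everywhere.
* **Leave-one-out consensus** removes whole individuals (all their
  samples), not single samples, because individuals are the biological
  replicates; a pair is retained only if significant *with the same sign*
  in every leave-one-out subset. Requiring sign agreement is stricter
  than requiring significance alone; we adopt it because a sign that
  depends on one individual is exactly what the procedure exists to
  exclude. Reported statistics come from the full-sample run.
* **Zero-variance** features cannot enter a correlation and are dropped
  with a warning; the pair is absent from the output rather than NA.

## Permutation validation

`random_geneset_null()` asks whether a focal gene set (e.g. KRAB-ZNFs)
has more significant TE correlations than size-matched random gene sets
drawn from an expressed-gene pool, recomputing the *identical* pipeline
(including BH within each draw) per iteration and reporting one-sided
empirical p-values with the plus-one rule
$p = (1 + \#\{null \ge obs\})/(1 + B)$, which can never be zero.
`evidence_overlap_test()` does the same for the Jaccard similarity
between significant pairs and a binding-evidence pair list, drawing
random pair sets from the stated universe. Evidence pairs are compared at
(gene symbol, TE subfamily) granularity; binding loci are out of scope.

Random gene sets are *not* expression-matched: matching would change the
null hypothesis (from "any random genes" to "random genes of similar
abundance"), and the claim being tested is the former. Fixing the seed
fixes the null draws bitwise, and results are independent of any worker
count because each iteration is a pure function of the draw.

A note on calibration testing: under a pure global null with the default
thresholds, the significant-correlation count is 0 in essentially every
draw, so the empirical p is identically 1 (total ties) and its uniformity
cannot be observed. The calibration experiment in the acceptance suite
therefore runs on data with a diffuse correlated background (one latent
sample factor with random loadings, `background_cor`) and permissive
thresholds, where the count statistic varies; exchangeability — the
property actually under test — holds regardless of thresholds.

## Evolutionary ages

Features at or below the 44.2 Mya split (the emergence of Simiiformes)
are young; the boundary value itself is young. A link is young when
*either* endpoint is young, old only when both are old; with the
correlation sign this gives the four classes P-O, P-Y, N-O, N-Y. Features
without an age (elements that cannot be placed on a branch) are excluded
from age-classified analyses with a warning rather than guessed.
Per-TE-family composition tests compare each family's 4-class counts
against the pooled counts of all other families (2×4 chi-squared,
$\alpha = 0.001$); when any expected cell is below 5 the asymptotic p is
replaced by a Monte-Carlo p (10^5 fixed-margin table simulations), since
sparse rows are the norm for rare families.

## Bipartite networks

Edges carry the signed correlation, but Barber's bipartite configuration
null model requires nonnegative weights, so modularity uses $|r|$ and the
sign lives in the link class:

$$Q_b = \frac{1}{m}\sum_{g,t}\left(A_{gt} - \frac{k_g d_t}{m}\right)
\delta(c_g, c_t).$$

`detect_modules()` seeds the partition with leading-eigenvector
communities on the gene-side unipartite projection (genes connected when
they share a TE, weight = sum over shared TEs of the smaller $|r|$ — the
standard bipartite-to-unipartite initialization), assigns each TE to its
best gene module, then alternates single-node sweeps (in fixed
lexicographic node order, accepting only strict $Q_b$ increases, with a
fresh-module move allowed) and pairwise module merges until neither
improves. Singleton and all-in-one starts plus eight seed-derived random
restarts are refined the same way and the best final partition kept; on
all random bipartite graphs up to 10 nodes that the suite enumerates
exhaustively, the returned $Q_b$ equals the global optimum. The procedure
is deterministic given the seed and node order.

Other network rules:

* **Normalized degree** divides a gene's degree by the number of TE
  nodes and vice versa, making the two unequal classes comparable.
  Bipartite betweenness is computed and exported as node metadata but
  does not feed hub calling.
* **Hubs** are the intersection of the top-5% lists by degree and by
  strength — stricter than either list alone. The cutoff is the k-th
  largest value with $k = \max(1, \lfloor 0.05\,n\rfloor)$ and ties at
  the cutoff are included; the floor (rather than ceiling) is what makes
  a 21-node star yield exactly its center rather than every tied leaf.
* **Module enrichment** uses a Monte-Carlo Fisher test (default $10^6$
  fixed-margin hypergeometric draws, two-sided by the minimum-likelihood
  rule, plus-one corrected) per module × category at $\alpha = 0.05$.

## Species and condition contrasts

Cross-species comparisons first restrict to the features expressed
(presence filter) in every species. Pair categories relative to the
reference group are assigned with the precedence sign_flip > conserved >
reference-specific ("human_specific"), and pairs not significant in the
reference are "other"; the precedence keeps the categories mutually
exclusive when a pair is, say, conserved with one species and flipped
with another. Condition-lost links are significant in control, not
significant in disease, and members of an externally supplied
reference-specific pair set; raw-sign agreement without significance is
deliberately not merged into these categories.

## The synthetic-data generator

`simulate_dataset()` draws negative-binomial counts through a Gaussian
copula: each feature has a latent standard normal per sample, a planted
pair's TE latent is $\rho z_{gene} + \sqrt{1-\rho^2}\,\varepsilon$ within
its species/condition scope, and counts are NB quantiles of the latent's
normal CDF, so the marginals are exactly NB while the planted rank
correlation is set analytically (the realized Pearson correlation on
counts is slightly attenuated by discretization; the suite asserts
planted $r = 0.9$ lands in [0.75, 0.98] at n = 24). The species scaling
factor multiplies the mean of every annotated feature, while an
*unscaled* background transcriptome (default 2,000 features) dominates
the library total — without such a background a global factor would be
absorbed by the library-size term and be unidentifiable from matrix sums,
exactly as in real data where the compared features are a minority of the
library.

Default design: four species with 4+3+3+3 individuals, seven region
groups, five samples per individual per group, ~340 KRAB-ZNFs among 1,000
genes and 900 TE subfamilies, 30% young features, NB dispersion 0.15 —
the shape of a multi-species brain cohort. The test and acceptance suites
run 5–10× smaller versions (e.g. 34 KRAB-ZNFs × 90 TEs, two region
groups) so the whole suite completes in about a minute; those sizes are
stated in the tests themselves.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: library-size variation between
samples (depth is uniform unless scaled), individual-level random effects
(samples are exchangeable within species, so the leave-one-out test's
robustness against outlier individuals is exercised with a separately
constructed fixture), unpaired case/control cohorts (conditions are
simulated within individuals), correlated TE families, compositional
effects, and mapping/quantification artifacts. Recovery results on this
generator validate the pipeline's logic, not the biology of any
particular dataset.

## Known limitations

* The DE module handles two-group contrasts only; no covariates.
* The scaling model assumes one global factor per species pair;
  length-dependent or GC-dependent biases are not modeled. More than two
  species are handled pairwise against a chosen reference.
* Exact binomial calibration degrades to factor *location* (not level
  calibration) under strong overdispersion, as described above.
* Monte-Carlo p-values (module enrichment, sparse family tests) have
  simulation error of order $1/\sqrt{n_{sim}}$; defaults keep this below
  the decision thresholds in use.
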