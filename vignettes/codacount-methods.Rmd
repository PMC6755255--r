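---
title: "Compositional analysis of sequencing counts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of sequencing counts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codacount)
```

## Why counts are compositions

A sequencer can only read a fixed number of fragments, so the total count of
a sample is set by the machine, not by the input material; the cell itself
imposes a second constraint through its finite capacity for RNA synthesis.
Both act as *closures*: they impose a constant-sum constraint that
irreversibly discards the absolute scale. What remains is a composition —
each feature is interpretable only relative to the others. Treating closed
counts as absolute abundances breaks independence assumptions, makes
distances erratic under feature inclusion/exclusion, and produces
correlations between features that are statistically independent.
Re-closures such as counts-per-million change the denominator, not the
nature of the data.

`codacount` implements a workflow that never normalizes. It transforms the
data relative to an explicit reference (differential abundance,
proportionality) or works on pairwise log-ratios where every scale factor
cancels (differential proportionality), and it models the technical
imprecision of small counts by Dirichlet Monte-Carlo sampling.

## Zero handling

Logs do not take zeros. We treat every sequencing zero as a *count zero* —
the feature was seen somewhere, so deeper sequencing would eventually see it
here — because rounding zeros do not occur in counting assays and no strict
compositional treatment of essential zeros exists; features believed truly
absent should simply be dropped. Two families are provided:

* **Feature removal** (`drop_zero_features`): features whose zero fraction
  exceeds a threshold are excluded, leaving a sub-composition. Ratios among
  the survivors are untouched.
* **Multiplicative replacement** (`simple_multiplicative_replace`,
  `bayesian_multiplicative_replace`): zeros receive a small positive
  proportion and the non-zero proportions are shrunk by the replaced mass,
  which preserves every observed ratio exactly — the property all later
  log-ratio analyses rely on. The Bayesian variant uses the Dirichlet
  posterior expectation `s_i * alpha_j / (n_i + s_i)`; the default prior is
  uniform weights `alpha_j = 1/D` with the square-root strength
  `s_i = sqrt(n_i)`. We chose this member of the prior family because it is
  fully determined by the data dimensions; geometric-Bayesian alternatives
  involve fitting steps and can be supplied through `prior_weights` and
  `prior_strength`. A warning is raised when a replaced value exceeds the
  smallest observed proportion in its sample (prior too strong).

Replacement happens before transformation; drop-then-replace is allowed.

## Log-ratio transformations

All single-feature inference is relative to a reference `g(x_j)`:

* **clr** — geometric mean of all features ("relative to the average");
* **alr / malr** — one or several named features (hypothesis-driven
  references such as a pathway hub or spike-in set);
* **iqlr** — features whose clr variance lies in the interquartile range, a
  robust average. Quantiles use the linear-interpolation convention
  (R type 7) with inclusive bounds, which decides edge membership;
* **rclr** — geometric mean over the non-zero features only; output cells
  at original zeros are `NA` and are never silently imputed;
* **ilr balances** — an orthonormal basis from a sequential binary
  partition; `sqrt(rs/(r+s)) * ln(g(num)/g(den))` per split. Euclidean
  distance between balance rows equals the Aitchison distance.

Natural log is used internally; differential-abundance outputs use base 2
so differences read as log2 fold differences, and the base is recorded on
every transformed table so views are never mixed. Transformed output is
deliberately never called "normalized": every report is phrased *relative
to* its reference, which is stored alongside the values.

The Aitchison distance (Euclidean on clr rows) is scale invariant and
sub-compositionally dominant — removing features can only shrink it — which
is why it, and not a distance on raw proportions, should feed clustering
and ordination.

## Dirichlet Monte-Carlo uncertainty

The difference between 1 and 2 counts is not the difference between 1,000
and 2,000: additive noise hits the low-count margin hardest, and the
relative value of a count zero spans orders of magnitude. Instead of a
point estimate, we draw `B` instances of each sample's proportion vector
from `Dirichlet(counts + prior)` (per-cell Gamma draws, row-normalized) and
report expected statistics across instances. Defaults: `prior = 0.5` mass
per cell, `B = 128`. Zero cells always receive strictly positive draws, so
the Dirichlet layer is itself a zero treatment.

## Differential abundance

`aldex_da` transforms each Dirichlet instance (base 2), runs a Welch
t-test per feature between the two groups, adjusts with Benjamini-Hochberg
*within the instance*, and reports the expectation of the adjusted p-value
across instances (never BH applied to averaged p-values). Per instance it
also computes the between-group difference of medians and a within-group
difference, sampled as the absolute difference between one random pair of
samples per group, taking the larger of the two groups; the effect size is
the per-instance ratio of the two, summarized by its median. One random
intra-group pair per instance was chosen over enumerating all pairs: it is
the cheapest unbiased probe of within-group spread, and the median over
128 instances stabilizes it. `diff_btw > 0` means higher in the second
group level, *relative to the reference*.

Choosing the reference is an interpretive act: with a clr reference a call
means "moves more than the average gene"; with a hub gene as alr reference
it means "moves more than the hub". The package makes the dependence
explicit and testable — shifting the reference by `delta` log2 units in one
group shifts every feature's `diff_btw` by exactly `-delta`.

Non-integer inputs (TPM-like units, quasi-counts) are ceiled before
Dirichlet sampling, with a warning, since the sampler needs count-like
totals. `linear_model_da` generalizes the t-test to any full-rank design by
per-instance ordinary least squares.

## Proportionality

For a feature pair, the variance of the log-ratio
`VLR = var(ln(x_g/x_h))` is reference-free and invariant to any per-sample
scaling, but has no scale of its own, so pairs are compared through
`rho = 1 - VLR/(var A_g + var A_h)` (in `[-1, 1]`),
`phi = VLR / var A_g` (asymmetric, stored directed), and the dissimilarity
`phi_s = (1 - rho)/(1 + rho)`, all computed on the transformed table `A`.
Significance is not parametric: `permutation_fdr` shuffles each feature's
values across samples independently — destroying inter-feature association
while preserving marginals — and estimates, for each cutoff on a grid
(default `seq(0, 1, 0.05)`, 100 permutations), the expected fraction of
passing pairs that the null alone would produce. A whole-row (sample)
shuffle would preserve the compositional coupling under test and was
rejected as a null. Counting is one-sided (`rho >= cutoff`); negative rho
is rare under clr and a negative-association screen would need its own
null. `expected_proportionality` averages the pair matrix over a Dirichlet
ensemble for low-count robustness.

## Differential proportionality

`theta_d` compares a pair's within-group log-ratio variance to its total:

`theta = [sum_k (N^k - 1) VLR^k] / [(n - 1) VLR_total]`

with `theta = 0` a maximal between-group ratio shift and `theta = 1` none.
The `(N^k - 1)/(n - 1)` weights are the one-way ANOVA decomposition of the
log-ratio; this identity is verified in the tests by checking that
`update_f`'s exact p-value — from `F = (n - 2)(1 - theta)/theta` on
`F(1, n - 2)` — equals the p-value of `anova(lm(log_ratio ~ group))` to
1e-9. BH correction across all pairs is mandatory and applied by
`update_f`. `lr_design_fit` extends the same idea to arbitrary designs
(e.g. adding a time covariate reveals time-dependent stoichiometry that a
group-only model misses). No reference is ever involved, so theta is
invariant under any per-sample rescaling.

With zeros, both pair modules accept a Box-Cox option: `ln(x)` is replaced
by `(x^alpha - 1)/alpha`, whose `alpha -> 0` limit recovers the log;
`alpha = 0.5` is a reasonable choice in the presence of zeros. This is a
pragmatic device outside the strict compositional framework (it is not
scale invariant), and the package applies the power transform inside the
log-ratio differences — a choice documented here because no canonical
formula exists.

## The synthetic generator

`simulate_absolute` builds strictly positive absolute abundances — the
quantity no sequencer observes — with planted structure, then
`sequence_counts` closes each sample to proportions and draws multinomial
counts at a per-sample depth. What it emulates: per-sample closure;
negative-binomial depth spread (fixed depth available for exact
conservation checks); count zeros arising naturally at low depth; a
log-normal per-sample capacity multiplier (the total-RNA analogue, e.g. a
high-capacity condition) that closure destroys — by design no method can
recover it, which is precisely the closure-bias point; planted
differential features (fold change in group 2); planted proportional
modules whose members are exact multiples of a shared latent factor
(absolute VLR exactly 0); planted differential-stoichiometry pairs whose
ratio mean shifts between groups; optional time-trend pairs in a
2-condition x time x replicate layout. Planted sets are allocated
disjointly, so the documented precedence (differential > stoichiometry >
module) never has to fire in practice.

What it does not emulate: read-level error, GC/length bias, batch effects
that hit only some genes, overdispersed biological networks beyond the
planted modules, and any mass-spectrometry-specific noise (a protein-like
layer can be produced with the same machinery plus extra log-normal noise —
a modelling convenience, not a calibrated instrument model). Passing tests
therefore demonstrate correctness of the algorithms under a controlled
generative model, not performance on any particular real dataset.

The standard fixture (`make_lps_like`) is a 28-sample x 1,000-feature
two-condition time course (7 time points x 2 replicates per condition),
50 four-fold differential features, 3 proportional modules of 5, 20
stoichiometry pairs with a 2-fold ratio shift, and mean depth 5e4 —
desk-scale sizes chosen so the entire suite exercises every stage, chosen
as representative of a small bulk experiment. All randomness flows from a
single integer seed through R's Mersenne-Twister generator; the same seed
reproduces every matrix bit for bit, and seeded helpers restore the
caller's RNG state.

## Numerical and statistical choices

* Geometric means are computed in log space to avoid overflow.
* Welch's t is evaluated vectorised from the defining formula (verified
  against `stats::t.test`); zero-variance groups degrade to `t = 0, p = 1`
  when means agree and `p = 0` (flagged infinite t) when they differ.
* `theta` is clamped to `[0, 1]` against floating-point excursions;
  `theta = 0` maps to `p = 0`, `theta = 1` to `F = 0, p = 1`; pairs with
  zero total variance are reported missing.
* Constant (zero-variance) features make rho undefined; their entries are
  `NA` with a warning rather than a silent 0 or 1.
* Null calibration of the exact F-test is checked by Kolmogorov–Smirnov on
  the *disjoint* pairs only (feature 1/2, 3/4, ...): p-values of pairs
  sharing a feature are mutually dependent, and a KS test pooled over all
  `D(D-1)/2` pairs rejects far too often even when the marginal
  distribution is exactly uniform. The pooled fraction below 0.05 is
  checked separately.
* The realized false-discovery proportion of the permutation-FDR screen is
  validated against a ground truth defined by applying the same metric and
  cutoff to the noiseless absolute abundances.

## Limitations

* Only two-group designs for `theta_d`; richer designs go through
  `lr_design_fit` / `linear_model_da`.
* The pair modules materialize `D x D` matrices; ~5,000 features is a
  comfortable ceiling on a laptop-class machine before block-wise
  computation would be needed.
* `rclr` missing values are propagated, and downstream modules currently
  refuse them rather than handling them pairwise.
* Balance partitions must be user-supplied; no tree-driven construction.
* No precision weights or moderated statistics; the exact F-test assumes
  approximately normal log-ratios, which very low counts violate — that is
  what the Dirichlet layer and the Box-Cox option are for.
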