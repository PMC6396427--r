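---
title: "Joint analysis of pooled CRISPR knockout screens with poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint analysis of pooled CRISPR knockout screens with poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The problem

Pooled CRISPR/Cas9 knockout screens measure the fitness cost of gene
knockouts by tracking guide RNA abundances through selection. Different
guides targeting the same gene routinely produce very different depletion
signals, because guides differ in how efficiently they produce a functional
knockout. Processed one screen at a time, this guide-level variability
inflates gene-effect uncertainty and forces large experiments. When several
screens are performed with the *same* guide library, however, a guide's
efficacy is a shared, condition-independent property, and modelling it
jointly across screens sharpens every individual screen's gene calls.

`poolscreen` fits exactly that joint model and provides the surrounding
machinery: normalization, empirical-Bayes noise priors, an empirical null
for significance calls, a ground-truth simulator, ranking metrics, and a
subsampling harness for experiment-design questions.

## Model

For guide $i$ of gene $g$ in condition (cell line) $l$, the observed
replicate-averaged log2 fold change is modelled as

$$ y_{gil} \sim \mathcal N\!\left(x_{gi}\, w_{gl},\ \tau_{gil}^{-1}\right), $$

with three sets of latent variables:

* $x_{gi}$ — guide efficacy, shared across conditions, prior
  $\mathcal N(\mu_x = 1, \sigma^2_x = 1)$: most guides are expected to work
  moderately well, and the prior regularizes guides seen in few informative
  conditions.
* $w_{gl}$ — gene essentiality in condition $l$ (log2 scale), prior
  $\mathcal N(\mu_w = 0, \sigma^2_w = 1000)$, i.e. essentially flat.
* $\tau_{gil}$ — observation precision, prior
  $\Gamma(a_{gil}, b_{gil})$ set empirically (below).

### Fold changes and normalization

Raw counts $t$ are transformed as $\log_2(t + 32)$ and each sequenced
replicate is centred by subtracting its median over all guides. The
pseudocount of 32 is a soft alternative to discarding low-count guides: it
caps the log fold change a poorly represented guide can show instead of
removing it. `y` is then the mean over treatment replicates minus the mean
over the associated control replicates. Control samples may be shared
between conditions (the common plasmid/early-timepoint layout); a condition
uses its own control rows from the sample sheet when present and the global
control group otherwise.

### Empirical-Bayes precision priors

With only two to four replicates, per-guide variance estimates are
unusable directly. Instead, per sample group the per-guide replicate means
and (population) variances are computed, pairs are sorted by mean, and each
variance is replaced by a moving average over the `min(800, 1% of guides)`
guides of closest mean (window floored at 1 so small test libraries remain
valid; truncated symmetrically at the ends of the sorted list to avoid
padding artifacts; ties in the sort broken by guide order for determinism).
A monotonicity correction then scans from the highest mean downward and
holds any step lower constant, so smoothed variance never increases with
abundance. The prior is $a = \kappa$, $b = \kappa(\hat\sigma^2_T +
\hat\sigma^2_C)$ with $\kappa = 0.5$, which makes the prior expected
variance of $y$ the sum of the smoothed treatment and control variances
while letting the data move individual precisions.

### Variational inference

A mean-field approximation $Q(x)\,Q(w)\,Q(\tau)$ is optimized by closed-form
coordinate updates; each sweep updates, in order, the precisions, the
efficacies, the identifiability normalization, and the essentialities:

* $Q(\tau_{gil}) = \Gamma(a + \tfrac12,\ b + \tfrac12\beta^*)$ with
  $\beta^* = y^2 - 2y\,\mathbb E[x]\,\mathbb E[w] + \mathbb E[x^2]\,\mathbb E[w^2]$;
* $Q(x_{gi})$ Gaussian with precision $1/\sigma^2_x + \sum_l \tau^*\mathbb E[w^2]$
  and mean $(\mu_x/\sigma^2_x + \sum_l \tau^* y\, \mathbb E[w])$ over that precision;
* $Q(w_{gl})$ Gaussian with precision $1/\sigma^2_w + \sum_i \tau^*\mathbb E[x^2]$
  (sum over the guides targeting $g$) and the corresponding mean.

The likelihood is unchanged by scaling $x$ up and $w$ down, so after each
efficacy update the means within each gene are rescaled so that their
*median-emphasized average* —
$(\sum_i \mathbb E[x_{gi}] + \mathrm{median} - \tfrac12\max - \tfrac12\min)/N_g$
— equals one. This reference point uses all guides but up-weights the
median and down-weights extremes. Both the means and the standard
deviations of $x$ are rescaled, and the gene's $w$ posterior is scaled
compensatorily so the fitted product $\mathbb E[x]\mathbb E[w]$ is exactly
preserved; leaving $w$ untouched would silently change the likelihood
mid-inference. A gene whose scale comes out zero or non-finite is left
unnormalized with a warning.

Numerical choices worth knowing:

* **Initialization** (deterministic): $\mathbb E[x] = 1$,
  $\mathrm{Var}[x] = \sigma^2_x$; $\mathbb E[w]$ starts at the per-gene mean
  of $y$ (the unit-efficacy least-squares solution) with zero variance for
  the first precision update.
* **Convergence** is declared when the maximum absolute change in
  $\mathbb E[w]$ between successive essentiality updates falls below `1e-4`
  (default), with a 50-sweep cap. The change is measured between successive
  update outputs, *before* the compensating rescale of the next sweep: the
  normalization applies a per-gene scale every pass, so comparing across the
  rescale would show a persistent offset even at the fixed point. At
  genome-ish scale the cap typically binds with residual changes around
  1e-3, which is inconsequential for gene ranking.
* **Degenerate precision**: if $b = 0$ and $\beta^* = 0$ (noiseless
  fixtures) the posterior rate is floored at machine epsilon and the
  precision capped at $10^6$.
* The inference itself contains no randomness; given inputs it is exactly
  reproducible.

### Hierarchical-prior (HP) variant

`mode = "hp"` re-sets each gene's essentiality prior before every update to
the mean of its current posterior means across conditions, with variance
three times their variance, floored at `hp_variance_floor`. This favours
consistent effects across lines and shrinks outlier conditions toward the
gene's consensus. The floor defaults to 0.01 (prior sd 0.1 on the log2
scale): with a much smaller floor the self-centred prior pins the estimate
so tightly that degenerate cases — identical conditions, or a single
condition where the cross-condition variance is zero — move only a tiny
fraction of the way to the fixed point per sweep and effectively freeze.
At 0.01 those cases converge within the iteration budget and the intended
shrinkage behaviour is unaffected.

### Fixed-efficacy single-screen mode

`mode = "fixed"` (or `predict()` on a fitted model) pins $Q(x)$ to exported
first and second moments and updates only $\tau$ and $w$, with no
normalization. Guides missing from the reference fall back to the prior
moments ($\mathbb E[x] = 1$, $\mathbb E[x^2] = 2$), with a warning when
coverage drops below half the library. On simulated data, refitting a
single condition with the joint fit's exported moments reproduces that
condition's essentialities with $r^2 > 0.999$.

## Significance against a resampled null

P-values require a set of negative controls: known-nonessential genes or
safe-targeting guides. Rather than using control genes directly — a few
mislabelled controls would distort the null — 2000 *pseudogenes* are
assembled: each draws its guide count from a random real gene and then that
many control guides without replacement (controls are reused across
pseudogenes). Resampling spreads any mislabelled guide's effect thinly
across many pseudogenes. The pseudogene grouping is scored by the same
variational machinery, reusing the already-computed fold changes and priors,
in isolation from the real genes.

Per condition, a Gaussian kernel density estimate with Scott's-rule
bandwidth ($\mathrm{sd} \cdot n^{-1/5}$) is fitted to the 2000 pseudogene
scores, and a gene's depletion p-value is the mass of that density below its
essentiality estimate. For a Gaussian-kernel KDE this lower-tail integral
has the exact closed form $\frac1n\sum_j \Phi\!\big((\hat w - \hat
w_j)/h\big)$, so no numeric quadrature is involved. Enrichment p-values are
emitted as the complement, for positive-selection screens. Benjamini-
Hochberg adjustment is applied within each condition, since the null is
condition-specific. With the resampling seed fixed, the whole significance
pass is bit-reproducible.

## The synthetic-screen generator

`simulate_screen()` generates the study conditions used throughout the test
suite, with full ground truth. Defaults (chosen once, as a realistic
desk-scale screen):

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `guides_per_gene` | 1000, 5 | library design |
| `n_conditions` | 10 | jointly analysed cell lines |
| `r_treatment`, `r_control` | 2, 1 | replicates; the control is shared across lines, as with a plasmid reference |
| `essential_fraction` | 0.2 | genes with a real knockout effect |
| `effect_mean`, `effect_sd` | −2, 1 | essential-gene log2 effects |
| `efficacy_sd` | 0.5 | true guide efficacy spread around 1, truncated at 0 |
| `control_abundance_log_mean`, `_sd` | log(500), 0.5 | lognormal library representation |
| `dispersion` | 0.05 | negative-binomial overdispersion of replicate counts |
| `context_fraction` | 0.2 | share of essential genes active in only a random subset of conditions |

Counts are negative-binomial around `abundance * 2^(x*w)`. The abundance
spread deserves a note: sdlog 0.5 corresponds to a 90th/10th-percentile
skew ratio of about 3.6, which matches the library-uniformity QC targets
screens are held to; a substantially wider spread would describe a failed
library prep, and because the pseudocount caps the observable depletion of
low-abundance guides it would also mostly stress the normalization rather
than the model. The negative-binomial noise is deliberate: it produces the
mean-dependent variance structure the empirical-Bayes smoothing was built
for.

What the generator does *not* emulate: copy-number artifacts, guide
sequence features, off-target effects, or batch structure between
replicates. Passing tests therefore demonstrate correctness of the
inference and calibration machinery under the model's own noise
assumptions, not robustness to those real-data pathologies.

`shuffle_line()` constructs the negative-control condition used to check
that the method does not hallucinate signal: per treatment replicate, the
median-normalized fold changes are permuted across all guides and converted
back to counts against each receiving guide's own control abundance. The
back-conversion adds the replicate's median offset back before rounding
(floored at zero) so that the identity permutation reproduces the original
counts to within rounding — the stated fold-change-plus-control recipe
alone would leave the counts shifted by the removed median.

## Evaluation metrics and experiment-size analysis

`ranking_accuracy()` is the area under the ROC curve restricted to false-
positive rates below 0.2, normalized by 0.2 ("0.2 pAUC"): 1 for perfect
separation of essential from nonessential genes, 0.1 in expectation for a
random ranking. Ties are grouped at a single threshold with trapezoidal
interpolation, which makes the random-score expectation exact in the limit.
The complement is the ranking error; full AUC (`fpr_max = 1`), the 0.1
pAUC, `recall_at_fdr()` and `delta_auc()` are exposed behind the same
interface since they rank methods equivalently. Scores are oriented
"lower = more essential" by default, with an explicit `direction` argument.

`mean_fc_baseline()` is the standard per-gene mean of guide fold changes —
the single-screen comparator. `subsample_experiment()` bootstrap-samples
coprocessed conditions (with replacement), keeps a chosen number of
treatment replicates per condition, subsamples guides without replacement
within genes, refits, and records the test condition's ranking accuracy —
the machinery behind experiment-size questions such as the 15/6 = 2.5-fold
cell-number reduction when moving from a 5-guide/3-replicate to a
3-guide/2-replicate design (`experiment_size_reduction()`).

## Known limitations

* **No copy-number correction.** Amplified regions distort depletion
  signals; pair with an upstream correction when analysing aneuploid lines.
* **Pseudocount saturation.** Depletion beyond roughly
  $\log_2(\text{abundance}/32 + 1)$ is censored by the pseudocount, which
  compresses efficacy estimates of the strongest guides; with a single
  shared control replicate, control noise is common to all of a guide's
  conditions and cannot be averaged away. On the default synthetic
  conditions these two effects bound the global rank recovery of guide
  efficacies at about 0.75–0.85 (Spearman, against scale-identifiable
  truth) even though the same inference recovers a noiseless decomposition
  essentially exactly.
* **No-signal genes overfit noise into efficacy.** For genes with no effect
  in any condition, the rank-one fit aligns $x$ with replicate noise, and
  the per-gene normalization can amplify the resulting means; their
  inflated $\sum\mathbb E[x^2]$ shrinks their essentiality posteriors
  relative to signal-carrying genes. This is intrinsic to the normalized
  decomposition (the fixed point does not depend on when the normalization
  is applied); on shuffled-line controls it shows up as ranking accuracy a
  few points above the random expectation. The pseudogene null inherits the
  same shrinkage and therefore remains calibrated.
* **Efficacies are identified only within genes.** Each gene's efficacy
  scale is fixed by convention (median-emphasized average = 1), so $x$
  comparisons across genes are meaningful only up to that convention.

## Problem sizes used in the test suite

The acceptance-level checks run the full study conditions (1000 genes × 5
guides × 10 conditions, 2000 pseudogenes, five shuffled lines) — a complete
pass takes well under a minute on a single core. Unit and property tests
use smaller instances (tens of genes, 1–6 conditions) chosen to exercise
each code path deterministically.
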