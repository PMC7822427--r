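---
title: "Methods: root-type morphology under single and combined abiotic stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root-type morphology under single and combined abiotic stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Drought and heat rarely occur alone in the field, and a plant's response to
their combination is frequently *nonadditive*: stronger (synergistic) or
weaker (antagonistic) than what the two single-stress responses predict.
Maize seedlings build their early root system from two embryonic axes — the
primary and the seminal root — each carrying postembryonic lateral roots,
and the four root types respond to stress independently. `rootstress`
implements the statistical chain used to dissect such an experiment: a
randomized complete design with four treatments (Control, Drought at 30% of
field capacity, Heat at 32 °C, and their Combination) and four replicate
plants per treatment, phenotyped per root type.

The package operates on a tidy per-plant table
(`plant_id, treatment, root_type, trait, value`) and never touches images:
the pipeline starts from measured trait values.

# Trait derivation

From raw measurements — length $L$ (cm), volume $V$ (cm³), root dry weight
$DW$ (g) and whole-plant dry weight $PDW$ (g) — `derive_traits()` computes

* root length ratio $RLR = L / PDW$ (cm g⁻¹), the plant's relative
  investment in soil exploration;
* root mass ratio $RMR = DW / PDW$ (g g⁻¹);
* fineness $RF = L / V$ (cm cm⁻³);
* tissue density $RTD = DW / V$ (g cm⁻³);
* branching density $BD$ = lateral count per cm of branching zone (axes),
  or the lateral count and average lateral length $L/\text{count}$
  (lateral types).

These satisfy the decomposition
$$RLR = \frac{RMR \times RF}{RTD}$$
exactly, per plant and root type, because
$(DW/PDW)(L/V)/(DW/V) = L/PDW$. The identity is property-tested on random
positive inputs and on every raw-level synthetic plant. Average lateral
length is defined here as total lateral length over lateral count; the
quantity is not standardized in the field, so the definition is stated
rather than assumed.

# The synthetic-data generator

No per-plant dataset is distributed with the experiment this package
models, so the generator is a first-class module, calibrated to the
published per-treatment summaries (mean, standard error, $n = 4$) that
`builtin_table_fixtures()` carries for all 42 root-type traits.

Two modes:

* **trait_level** — each plant's trait value is an independent draw from
  $\mathcal N(\bar x, \mathrm{SE}\sqrt n)$, resampled until positive. Only
  the two published moments are available, so a truncated normal is the
  simplest law matching them; plant-to-plant variation of the real
  experiment is *assumed*, not known, to be normal.
* **raw_level** — raw measurements are drawn so derived traits are centred
  on the published values while the algebraic identities hold exactly.
  Per plant, whole-plant dry weight comes first
  ($PDW$ target = mean over root types of
  $\overline{DW}/\overline{RMR}$, with a 10% coefficient of variation),
  then per root type $DW = PDW \times RMR^{\ast}$,
  $L = PDW \times RLR^{\ast}$, $V = L / RF^{\ast}$, where starred
  quantities are truncated-normal draws from the published cells. Lateral
  counts are rounded positive draws; axis branching zones are clipped so
  root-zone + branching-zone ≤ length. The shoot dry weight closes the
  budget ($ShDW = PDW - \sum DW$) and shoot fresh weight uses a fresh:dry
  ratio of 9, a typical value for well-watered maize seedlings.

The published cells themselves are not mutually consistent with the RLR
identity (rounding in the source tables), so the generator matches the
$RMR$, $RLR$ and $RF$ draws and lets tissue density follow from the
identity; simultaneous exact matching of all four ratio traits is
impossible and not attempted. Treatments are pure labels: no soil physics,
water balance or temperature response is simulated. What passing tests on
these data show is that the *statistical machinery* behaves correctly under
the study's design and noise levels — not that real maize roots behave
normally.

Determinism: the dataset is a pure function of the configuration, whose
seed is mandatory.

# Univariate screen

Each root type × trait is tested by classical one-way ANOVA
(`stats::oneway.test`, equal variances) across treatments at
$\alpha = 0.05$, followed by Tukey's honestly-significant-difference
comparisons (`stats::TukeyHSD`, Tukey–Kramer under imbalance) and a compact
letter display. Letters are assigned by insert-and-absorb: start with one
letter covering all treatments; for each significant pair, split every
letter containing both and absorb subsets; order letters so the largest
mean carries "a", the convention of published trait tables. Non-transitive
significance patterns are representable (a treatment can hold several
letters) and round-trip exactly: regenerating the significance relation
from the letters returns the input relation.

The screen reports two counting conventions side by side — traits
significant by ANOVA, and traits whose letter set is disjoint from
Control's — because summaries in the literature mix the two.
Zero-variance traits are flagged as degenerate rows, not errors.

# Combined-stress interaction classification

For each trait the observed effect size of a combined-treatment plant is
$$Ob = \left|\frac{ob - \bar x_{Con}}{\bar x_{Con}}\right|,$$
and each single stress contributes an independent effect size
$Ind = |\bar x_{stress} - \bar x_{Con}| / \bar x_{Con}$. The additive
expectation uses the multiplicative risk model
$$Ex = Ind_D + Ind_H - Ind_D \times Ind_H,$$
which removes the over-inflated response of a plain sum and saturates at 1
when both effects are complete. $Ex$ is a scalar from treatment means, so
only $Ob$ varies across plants; the per-plant differences $Ob_i - Ex$ get a
two-sided 95% Student-t interval ($n-1$ df). Entirely above zero ⇒
synergistic, entirely below ⇒ antagonistic, otherwise additive. The source
method does not state whether its interval was t-based or bootstrap; both
are implemented (`method = "bootstrap"` gives a seeded percentile
bootstrap) and t is the default. Because effect sizes are absolute values,
the direction of the raw change (increase/decrease) is tracked separately
for reporting.

`interaction_screen()` classifies only traits whose Combined letter differs
from Control's in the univariate screen — the selected-traits workflow —
unless `eligibility = "all"`.

Effect sizes are scale-invariant (multiplying a trait by a constant changes
nothing), and the deterministic mean-level skeleton
(`effect_size_table()`) applied to the built-in published cells reproduces
the six nonadditive directions reported for this experiment: antagonistic
for primary-root fineness and branching density, synergistic for
primary-lateral length, surface area and RLR and for seminal-lateral
length.

# PERMANOVA

`permanova()` is written from scratch on squared inter-point distances:
$SS_{total} = \sum_{i<j} d_{ij}^2 / N$, within-group sums analogously per
group, pseudo-$F = (SS_{between}/df_B)/(SS_{within}/df_W)$, and the p-value
from free permutation of all sample labels with the observed statistic
included in the reference set ($p \ge 1/(B+1)$; $B = 999$ by default). The
distance metric is configurable; the default is Euclidean on z-scored
traits, the standard choice for morphometric (non-compositional) data —
and it makes the one-dimensional case algebraically identical to one-way
ANOVA, which the tests exploit as a cross-module oracle (and
`vegan::adonis2` as an external one). Pairwise contrasts rerun the test on
each pair's samples and correct across the $\binom{k}{2}$ pairs by
Benjamini–Hochberg (`stats::p.adjust`). Which traits enter the
multivariate stage is configurable; the default is all root-type derived
traits, since the source analysis does not enumerate its trait set.
No strata and no dispersion (PERMDISP) test are provided.

# Sparse PLS-DA

`fit_splsda()` implements NIPALS-style partial least squares against the
centered class-indicator matrix with per-component soft-thresholding of
the X-weight vector: per component, alternate $w \gets M v$ (with
$M = X^\top Y$), soft-threshold $w$ so `keepX` entries survive
(subtracting the largest magnitude strictly below the keep-th, so boundary
ties are all retained), renormalize, update $v$; then extract the score
$t = Xw$ and deflate both $X$ and $Y$ by their rank-one regressions on
$t$, which makes successive scores orthogonal. Columns of $X$ are centered
and unit-variance scaled (traits carry mixed units); the indicator matrix
is centered but not sparsified — only the number of *root traits* per
component is tuned. Component signs are anchored on the class loading with
the largest magnitude, so scores do not depend on arbitrary sign flips of
trait columns. With `keepX = p` the iteration converges to the dense
PLS-DA solution (`fit_plsda()`, computed directly from the leading
singular pair), a degeneracy the tests assert at $10^{-8}$.

Prediction projects new samples through the stored scaling and sequential
deflation and assigns the nearest class centroid in score space (Euclidean;
ties break to the first class level). Model selection follows the
perf/tune protocol: `perf()` runs repeated stratified k-fold
cross-validation of dense PLS-DA over component counts, reporting overall
and balanced error rates (BER — the mean over classes of each class's
misclassification fraction, insensitive to imbalance); `tune()` selects
per component, greedily, the smallest `keepX` attaining the minimal mean
BER (parsimony tie-break; a "within one SE of the minimum" rule is the
documented alternative). Defaults are 5 folds × 50 repeats; with 4
replicates per class, 5-fold stratification is impossible and folds are
reduced to the smallest class size with a warning — a wrinkle the source
protocol leaves unstated. Every stochastic operation requires an explicit
seed; repeat $r$ uses stream seed + $r$.

Explained X-variance per component is the squared-norm drop of the
deflated matrix (equivalently $\|t\|^2\|p\|^2 / \|X_0\|^2$), tested
against an explicit residual-norm oracle. `loading_group_assignment()`
reproduces the loading-plot coloring rule: each selected trait is assigned
the class whose group mean of the scaled trait is maximal (minimal for
negative loadings). `correlate_scores()` adds Pearson correlations of the
latent scores with plant fresh/dry weight.

On synthetic data calibrated to the built-in tables, component 1 separates
the Combined treatment from Control in most seeds — the qualitative
pattern reported for the real experiment. The real experiment's numerical
endpoints (52% total explained variance split 27/14/11%, BER ≈ 0.18,
overall PERMANOVA $R^2 = 0.6693$) are *not* exact targets here: the raw
per-plant data are unavailable, so only quantities recomputable from
published cells are asserted exactly.

# Numerical and design choices

* $\alpha = 0.05$ everywhere, matching the source protocol.
* Truncated-normal draws resample up to 100 rounds; a configured
  mean ≪ SD is a configuration error, not silent censoring.
* `soft_threshold_keep` refuses all-zero vectors; boundary ties retain all
  tied entries (support may exceed `keepX`).
* Permutation p-values can never be zero (+1/+1 rule).
* The tune grid defaults to {1..5, 10, p}; the maximum component count
  assessed by `perf` defaults to 5.
* Problem sizes used by the test-suite simulations: 1 000 replicates for
  type-I-error and permutation-null calibration, 10 000 plants per
  treatment for generator moment checks, 50 seeded runs for sparsity
  recovery — sizes at which Monte-Carlo error is comfortably inside the
  asserted tolerances.
* The planted-signal recovery fixtures give each of three informative
  traits a class contrast with four distinct values, so a single trait per
  component suffices for classification — the sparsity structure the
  method is meant to recover; ties in mean BER then resolve to the
  parsimonious `keepX = 1` by construction of the tie-break.

# Limitations

* The generator reproduces means and standard errors, not the real
  experiment's trait covariance across root types; multivariate results on
  synthetic data are therefore qualitative, not quantitative, analogues.
* The interaction classifier is defined for exactly two stressors; the
  multiplicative risk combination of three or more is not defined here.
* No mixed models, repeated measures, nested permutation strata or
  multilevel sPLS-DA.
* With $n = 4$ per treatment, the t-based interval on $Ob - Ex$ has 3
  degrees of freedom; classifications near the boundary are sensitive to
  single plants, which is inherent to the design, not the implementation.
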