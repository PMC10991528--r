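---
title: "Auditing and mitigating group bias in clinical risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and mitigating group bias in clinical risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Binary risk prediction models trained on pooled clinical cohorts often
perform unevenly across demographic subgroups. Depression screening is a
canonical example: outcome prevalence differs strongly between groups
(women are roughly twice as likely as men to develop depression), so a
model trained on the pooled data learns to assign systematically lower
probabilities to members of low-prevalence groups. At a single decision
threshold this translates into a lower true-positive rate (TPR) for those
groups — exactly the people who then fail to be referred for care.

`fairdep` packages the pieces needed to measure this effect and to act on
it: group-fairness metrics, five mitigation techniques (three
pre-processing, two post-processing), a cross-validated evaluation
protocol, and a synthetic cohort generator so that the whole pipeline can
be exercised without access to restricted patient-level data.

## Data model

A dataset is treated as a triple: categorical protected attributes $X$
(sex, ethnicity, income band, comorbidity, ...), descriptive features $Y$,
and a binary outcome $C \in \{0, 1\}$ with 1 the condition present. A
subgroup is the set of samples sharing one category $x \in \Omega_X$.
Missing protected values are never dropped or imputed: they form an
explicit `"Missing"` category, because in real cohorts the
prefer-not-to-answer group is often the one treated worst by the model and
must be auditable. Category order is lexicographic throughout, purely for
reproducibility.

For questionnaire-based outcomes the package ships the standard PHQ-9
rule: a 9-item total of 10 or more (out of 27) defines the positive class
(`phq9_binarize()`).

## Metrics

With $\hat C$ the model's hard prediction, the subgroup rates are

$$\mathrm{TPR}_x = P(\hat C = 1 \mid C = 1, X = x), \qquad
  \mathrm{FPR}_x = P(\hat C = 1 \mid C = 0, X = x).$$

* **EOD** (equal opportunity difference):
  $\min_x \mathrm{TPR}_x - \max_x \mathrm{TPR}_x$. Zero means all
  subgroup TPRs coincide; the value is never positive, and more negative
  means more biased. A conventional working band regards $|\mathrm{EOD}|
  \le 0.1$ as acceptable (`eod_within_band()`), exposed as a labelled
  predicate, not a hard-coded policy.
* **AOD** (average odds difference):
  $\tfrac12\left[\min_x(\mathrm{TPR}_x + \mathrm{FPR}_x) -
  \max_x(\mathrm{TPR}_x + \mathrm{FPR}_x)\right]$, the equalized-odds
  analogue.
* **BAcc**: the arithmetic mean of sensitivity and specificity, the
  appropriate accuracy summary for heavily imbalanced outcomes evaluated
  at a fixed threshold.
* **AUC-ROC**, computed as the rank statistic
  $P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$.
* **Fairness-accuracy score**:
  $$\Delta = \frac{(1+\beta^2)\,\mathrm{BAcc}\,(1-|\mathrm{EOD}|)}
                  {\beta^2\,\mathrm{BAcc} + (1-|\mathrm{EOD}|)},$$
  a weighted harmonic mean with $\beta = 0.5$ by default, weighing
  predictive performance above fairness — in screening, trading away true
  positives for parity has its own ethical cost. $\beta \to 0$ recovers
  BAcc exactly.

A subgroup rate whose conditioning set is empty (no positives, or no
negatives, in the group) is reported as an explicit undefined flag rather
than silently as zero or dropped; metrics that need it raise an error.
Silent handling would hide precisely the smallest subgroups.

Two statistical diagnostics round this out. `tukey_pairwise()` applies the
studentized-range (honest significant difference) procedure to per-fold
subgroup rates, treating cross-validation folds as replicates in a
balanced one-way layout — an approximation, since folds share training
data, but the standard way such intervals are produced in practice; with
zero within-fold variance the intervals degenerate to width zero with a
warning. `mannwhitney_disparity()` compares two score samples with the
Mann-Whitney U statistic (ties at half weight), with exact enumeration of
the null distribution when the pooled sample has at most 20 observations
and a tie-corrected, continuity-corrected normal approximation otherwise —
the exact path is deliberately capped to keep runtimes flat.

## The five mitigation techniques

**Suppression (SUP)** removes the protected attribute from the model's
view (`suppress_attributes()`). The attribute stays in the cohort for
evaluation. This is the baseline blinding intervention; it does nothing
about features *correlated* with the attribute.

**Reweighing (RW)** (`reweigh()`) gives each (group, label) cell the
weight $w(x,c) = \hat P(C=c)/\hat P(C=c \mid X=x)$, which makes the
protected attribute and the outcome exactly independent in the weighted
empirical distribution. The weighted mass equals the sample count and
every group's weighted prevalence equals the overall prevalence — both are
tested as exact identities. The attribute itself stays among the model
features: the point of RW is to neutralize the label association, not to
blind the model.

**Disparate impact removal (DIR)** (`dir_fit()` / `dir_apply()`) maps
every numeric/ordinal feature value through its own subgroup's empirical
quantile function onto a common target distribution, defined per rank as
the median of the group quantiles. At repair level $\lambda = 1$ the
subgroup distributions coincide up to discretization; $\lambda = 0$ is the
identity; intermediate values interpolate. Categorical features pass
through untouched — quantiles of unordered categories are undefined — and
the treated attribute is excluded from the output feature set. The repair
model is fitted on training data only and applied to held-out data through
the stored training quantiles.

**Calibrated equalized-odds post-processing (CPP)** (`cpp_fit()` /
`cpp_apply()`) operates on calibrated scores. Its cost is the generalized
false-negative rate $g_x = E[1 - s \mid C=1, X=x]$ — chosen because in
screening, recall matters more than precision. Each group with $g_x$ below
the maximum is mixed with its trivial base-rate predictor: a seeded random
fraction $\alpha_x = (g_{\max} - g_x)/((1-\mathrm{base}_x) - g_x)$ of its
samples has the score replaced by the group's base rate, which equalizes
the expected costs. Mixing destroys information for the better-off group;
that is the price of this family of methods, and the reason its balanced
accuracy tends to dip.

**Population sensitivity-guided threshold adjustment (PSTA)**
(`psta_fit()` / `psta_apply()`) is the package's per-group threshold
method. On training data, with reference threshold $t_0 = 0.5$:

1. compute the overall sensitivity $S^\*$ and overall FPR $F^\*$ at $t_0$;
2. a group whose training sensitivity at $t_0$ already reaches $S^\*$ is
   *privileged* and keeps $t_0$;
3. every other group receives the **largest** threshold $t \le t_0$ among
   its observed positive-sample scores (plus $t_0$) such that the group's
   sensitivity at $t$ reaches $S^\*$ and its FPR stays within $F^\* +
   \delta$ (default $\delta = 0.10$);
4. if no candidate satisfies both constraints, the candidate with maximal
   sensitivity subject to the FPR cap is taken (largest $t$ on ties); if
   even $t_0$ violates the cap the group keeps $t_0$ with a warning.

Choosing the *largest* qualifying threshold meets the sensitivity target
with the least FPR inflation. The candidate set is restricted to observed
positive scores because sensitivity only changes at those points; the
search is therefore exhaustive over all distinct outcomes, and the test
suite verifies it against an independent grid-scan oracle. Unprivileged
groups are identified by training sensitivity strictly below the overall
value; every such group is treated, consistent with the goal of helping
the most disadvantaged groups rather than only the single worst. Groups
without positive training samples cannot be aligned and keep $t_0$. At
apply time, $\hat C = 1$ iff the score reaches its group's threshold;
scores themselves are unchanged. Both $t_0$ and $\delta$ are exposed as
hyperparameters.

PSTA deliberately contrasts with CPP: it intervenes only on under-served
groups and only via the decision rule, accepting a bounded FPR increase in
exchange for sensitivity parity — suitable for primary-care screening
where missed cases are the dominant harm.

## Evaluation protocol

`run_scenario()` evaluates one (model, mitigation, attribute) cell under
stratified outer $k$-fold cross-validation (default $k = 10$; 5 is
appropriate for very large cohorts). Stratification on the outcome label
stabilizes subgroup rate estimates at low prevalence. Per fold:
pre-processing is applied to the training split only (repair models are
fitted on training data and applied to both splits); the model — ridge
logistic regression via glmnet with its penalty tuned over the grid
$\{10^{-1}, \dots, 10^{-4}\}$ by inner cross-validation, or gradient
boosted trees via xgboost with a small depth/learning-rate grid — is fitted
with any mitigation weights; post-processing policies are fitted on the
training predictions only; all metrics are computed on the held-out fold.
Folds missing a class are skipped with a warning, and a scenario with more
than half its folds skipped errors out. Summaries report the fold mean,
SD, and a normal-approximation 95% CI; Tukey simultaneous intervals are
available for pairwise subgroup-rate claims, since the two kinds of
interval answer different questions.

Everything is deterministic given the spec's seed: fold assignment, model
fitting (single-threaded xgboost), and mixing randomness all derive from
it, and `scenario_result_json()` output is byte-identical across reruns.
Provenance records the spec hash and seeds; no wall-clock timestamps, so
serialized results can be compared directly.

`compare_methods()` recomputes $\Delta$ per fold, declares per-cell
winners (exact ties are shared and flagged — there is no principled
tie-break), and tallies win percentages. `spillover_analysis()` reports
the change in $|\mathrm{EOD}|$ and $|\mathrm{AOD}|$ for *untreated*
protected attributes relative to the base model, positive meaning fairness
worsened — mitigation aimed at one attribute can shift outcomes for
correlated attributes in either direction.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure that drives the
bias of interest, not the semantics of any real cohort:

* **Group-dependent prevalence.** Outcomes are Bernoulli with logistic
  probability; a per-group intercept is solved by bisection so each
  group's expected prevalence matches its target exactly. The default sex
  prevalences (0.08 vs 0.04) encode the familiar two-to-one ratio;
  evaluation scenarios in this package use 0.10 vs 0.04.
* **Informative features** are standard normal with geometrically decaying
  coefficients `effect_scale * 0.8^(k-1)`.
* **Proxy features** are Gaussian with group-shifted means calibrated so
  their correlation with the protected attribute equals `proxy_strength`,
  and they carry a direct outcome coefficient (`proxy_effect`). This
  last point is deliberate: it routes most of the between-group prevalence
  gap *through* observable features. If instead the entire gap sits in a
  latent group intercept, blinding interventions (SUP, DIR) do not merely
  fail — they overshoot and reverse the disparity, because after blinding
  the low-prevalence group's positives are the ones with the more extreme
  feature values. Proxy mediation is the simplest mechanism under which
  suppression is insufficient (the signal survives in the proxies) while
  distributional repair is effective (merging the proxy distributions
  removes it).
* **Multiple attributes** can be coupled through a Gaussian copula
  (`attr_correlation`) to study spillover.

The defaults `effect_scale = 0.8`, `proxy_effect = 0.6` were fixed so that
the base logistic model on the default cohort shows the qualitative
pattern of interest — a clearly negative EOD against the low-prevalence
group, suppression leaving substantial residual unfairness, and
reweighing/repair/threshold adjustment reducing it without material
accuracy loss — with base balanced accuracy in a modest, screening-like
range. No claim of calibration to any real cohort is made: the real
cohorts' feature effect sizes are not public, and the generator's feature
semantics are abstract.

`generate_scored_population()` skips the modelling step entirely and draws
per-group score distributions directly (truncated normals on $[0,1]$, so
the location parameter reads as a probability), emulating the group-shifted
predicted-probability distributions that prevalence discrepancies produce.
This is the fixture for post-processing methods, whose inputs are scores,
not features.

What passing tests on these cohorts does **not** show: robustness to
real-data pathologies — label noise (questionnaire outcomes are noisy by
construction), informative missingness in features, survey weighting,
longitudinal structure, or categorical features with many rare levels.
The generator is a mechanism model, not a cohort simulator.

## Numerical choices and degenerate inputs

* Group intercepts: bisection on $[-30, 30]$ to $10^{-12}$.
* Proxy calibration: the group code is centered and scaled from the
  configured mixture proportions, and the proxy loading solves the
  population correlation identity; `proxy_strength = 1` degenerates to
  the code itself.
* DIR quantiles: inverse empirical CDF (type-1, step) with ranks clamped
  to $[1/n_g, 1]$; held-out values are ranked against the training
  distribution. With two groups the per-rank median is the midpoint.
* PSTA thresholds are kept in $(0, 1]$; candidate scores at 0 are
  excluded so that a threshold always classifies *some* region negative.
* Mann-Whitney: exact enumeration up to pooled $n = 20$
  ($\binom{20}{10} \approx 1.8 \times 10^5$ assignments), normal
  approximation beyond.
* Tukey with zero residual variance: width-zero intervals, any non-zero
  difference flagged, with a warning.
* Undefined rates (empty conditioning sets) propagate as flags; EOD/AOD
  require at least two defined groups and error otherwise.
* Single-class training folds are refused by `train_model()`; the
  scenario runner skips such folds with a warning.
* Feature matrices: categorical columns are one-hot encoded against
  levels frozen at fit time; numeric missing values take the training
  median (a deliberately simple constant-fill option — the package does
  not claim a missing-data strategy).

## Problem sizes

The bundled test suite and acceptance computation run the full protocol on
cohorts of $n = 20000$ with 10-fold outer cross-validation, ten
replicate seeds for the end-to-end mitigation property, and 5000 samples
per group for the distributional-repair checks. These sizes were chosen
as the smallest at which subgroup rate estimates for a 4%-prevalence
group are stable enough for the comparisons to be meaningful.

## Known limitations

* Mitigation treats a single protected attribute at a time; intersectional
  (multi-attribute) mitigation is out of scope, though the metrics can be
  applied to any categorical attribute, including manually constructed
  intersections.
* CPP assumes calibrated scores; applying it to poorly calibrated models
  equalizes a cost that no longer means what it should.
* PSTA thresholds for very small subgroups inherit the noise of their
  training sensitivity estimates; the method cannot help a group with no
  observed positives.
* The Tukey procedure over CV folds ignores fold dependence, as it
  usually does in applied work; its intervals are approximate.
* In-processing (model-internal) debiasing is deliberately absent: the
  package is model-agnostic by design and delegates model internals to
  glmnet and xgboost.
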