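---
title: "Predicting excess hospital length of stay with constrained neural networks"
author: "losnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting excess hospital length of stay with constrained neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(losnet)
```

## The problem

Hospital departments of internal and emergency medicine lose bed capacity to
hospitalizations that run past their expected duration. Italian hospitals have
two national references per DRG (Diagnosis Related Group): the *benchmark*,
the national mean length of stay (LOS) published annually, and the
*threshold*, a fixed ministerial cutoff above which a stay is an
administrative *outlier*. A stay strictly longer than its DRG benchmark is a
*long* hospitalization; a stay strictly longer than the threshold is an
outlier. Because every threshold exceeds its benchmark, outliers are a subset
of the long stays, and the two outcomes bracket the interval within which
discharge interventions can plausibly act.

`losnet` implements, end to end, a pipeline that (i) predicts these two
binary outcomes at admission time from routinely collected administrative
covariates, (ii) explains the trained predictor, and (iii) converts predicted
excess stays into an opportunity cost: freed bed-days, additional
hospitalizations and additional reimbursement revenue under the assumption of
fully efficient interventions.

## The prediction model

The predictor is a single-hidden-layer feed-forward perceptron trained by
back-propagation. One hidden layer suffices by the universal-approximation
argument, and keeping the architecture minimal preserves direct access to the
synaptic weights, which the interpretation layer requires. For input vector
$x \in \{0,1\}^p$ the network computes the linear-output score

$$\hat y(x) = b_0 + \sum_{j=1}^{h} v_j\,\sigma\!\left(\sum_{i=1}^{p} w_{ij} x_i + b_j\right),$$

with $\sigma$ either the hyperbolic-tangent sigmoid
(`tansig`, $2/(1+e^{-2z})-1$) or the logistic sigmoid (`logsig`,
$1/(1+e^{-z})$); the two satisfy $\mathrm{tansig}(z) = 2\,\mathrm{logsig}(2z)-1$,
which the test suite asserts numerically. Targets are coded 0/1 and a score
at or above 0.5 predicts the positive class (the boundary predicts 1; the
cutoff is a documented convention, not a tuned quantity).

Inputs are one-hot dummies in a fixed, documented block order: sex (1), age
class (4), cancer (1), admission type (3), admission time slot (3), weekday
(7) and principal-diagnosis group (the 10 most frequent groups plus one
residual class, 11 columns). No reference level is dropped: a neural network
needs no identifiability constraint, and full dummy blocks make every
categorical block sum to exactly 1 per row. Unit-level ("micro") models add
the internal-transfer indicator (31 columns instead of 30) and recompute the
top-10 diagnosis groups on the unit's own records. Ties at the top-10 rank
boundary break lexicographically so the encoding is deterministic.

### Training

Training minimizes the mean-squared output error over the training set by
full-batch gradient descent with a variable learning rate in the classic
adaptive style: the step grows by 5% after each successful epoch and shrinks
by 30% — with the step rejected — when the error would rise by more than 4%.
Step rejection keeps the recorded training error non-increasing up to that
tolerance, and the analytic gradient is validated against central finite
differences to $10^{-6}$ in the tests. Weights initialize uniformly on
$(-0.5, 0.5)$ from a seeded generator, so every fit is reproducible.
Training stops at a predefined error threshold (default $10^{-4}$ MSE) or at
`max_epochs` (default 2000). The hidden-layer size must be found
empirically; when not supplied it is chosen over the grid
$\{\lceil p/2\rceil,\, p,\, 2p+1\}$ by validation balanced accuracy, with
ties to the smaller network.

### Constrained bootstrap selection

The cohort is split 2/3 training, 1/3 validation, stratified by the outcome
so both classes appear in both parts. The selection algorithm then runs a
fixed number of bootstrap replications (default 100): each resamples the
training rows with replacement and retrains from a fresh seeded
initialization. Sensitivity and specificity of every replication are
measured on the full training sample; replications meeting the ex-ante
floors (sensitivity $\ge 0.80$, specificity $\ge 0.70$ by default) form the
eligible set, and the eligible replication maximizing the oriented metric —
the analyst chooses whether to favor true positives or true negatives — is
selected, ties going to the smaller replication id. If no replication meets
the floors the oriented maximum is returned with a warning and
`floors_met = FALSE`. The validation sample is touched exactly once, to
produce the reported evaluation; the split is fixed across replications, and
validation rows never enter any resample (asserted in the tests).

Two open choices were resolved as follows and are deliberate package
conventions: floors are checked on the training sample because selection
operates in the training phase, and the reported metrics come from the
single selected network rather than an average over replications (the
replication-wise metric distribution is returned alongside for inspection).

## The evaluation report

`evaluate()` reports the eight diagnostic indexes: incorrect classification
$((1-\mathrm{sens})\cdot m + (1-\mathrm{spec})\cdot(n-m))/n$ with $m$ the
number of actual positives, sensitivity, specificity, false positive rate
(Type I), false negative rate (Type II), the likelihood ratios
$LR^+ = \mathrm{sens}/(1-\mathrm{spec})$ and
$LR^- = (1-\mathrm{sens})/\mathrm{spec}$, and the AUC. For a classifier
evaluated at a single cutoff the ROC has one interior point, so the area
under the piecewise-linear curve is $(\mathrm{sens}+\mathrm{spec})/2$; this
identity is the reported `auc_binary` (a score-based trapezoidal AUC is also
available and is cross-checked against pROC in the tests). Standard errors
are binomial Wald, $\sqrt{p(1-p)/m}$, with 95% intervals built as
$p \mp 1.96\,\mathrm{SE}_3$ where $\mathrm{SE}_3$ is the SE rounded to three
decimals — the convention that makes a printed (SE, CI) pair internally
consistent. Reported percentages round half away from zero.

## Interpretation

Variable importance uses Garson's absolute-weight decomposition: for input
$i$ and hidden node $j$, $c_{ij} = |w_{ij}||v_j|$ is normalized within each
hidden node, summed over nodes and rescaled to percentages summing to 100.
Hidden nodes with zero total inflow are skipped, and the output bias is
excluded because it carries no input information. Each dummy column is
scored separately, so e.g. the afternoon and night admission slots get their
own percentages. The direction of each input's effect is the sign of its
summed connection-weight products $\sum_j w_{ij} v_j$ (the Olden-style
quantity): positive means the input raises the predicted probability of the
outcome. Both quantities are pure functions of the weights, hence exactly
reproducible from a serialized model file.

## The economic simulation

Given predictions on a held-out year, the impact module assumes fully
efficient interventions: every predicted-positive stay is shortened to its
DRG benchmark (`reduce_to = "threshold"` is available for the conservative
variant), via `min(LOS, benchmark)` so that false positives below the
benchmark cost nothing. Per group (clinical unit, diagnosis group, diagnosis
code, or overall),

* freed bed-days $= \mathrm{round}(n \cdot (\bar L_{obs} - \bar L_{sup}))$,
* additional hospitalizations $= \mathrm{round}(\text{unrounded days} / \bar L_{sup})$,
* additional revenue $=$ additional hospitalizations $\times$ the group's
  case-mix mean DRG reimbursement,

where $\bar L_{sup}$ is the post-intervention mean LOS and rounding is half
away from zero, applied after aggregation. Dividing by the *supported* mean
is the convention that reproduces the published group arithmetic (e.g.
581 heart-failure stays with means 9.669 → 7.195 days free
$581 \times 2.474 = 1437.4$ days, i.e. $1437.4/7.195 \approx 200$ additional
hospitalizations). The revenue rule is a case-mix average because the exact
tariff accounting behind published department totals is not reconstructible;
totals therefore scale with the tariff table supplied.

## The synthetic cohort generator

Real administrative admission data are not redistributable, so the package
ships a generator that emulates the published department's marginal
structure and serves as the test bed for every downstream stage. Covariates
are categorical, drawn independently *within* each clinical unit at the
published per-unit prevalences (whole-department values for units without
published columns); the default unit mix is proportional to the published
per-unit validation volumes. Length of stay is log-normal with additive
effects on the log mean:

$$\log L = \mu_{DRG} + \textstyle\sum_b \beta_{b(x)} + \sigma Z,$$

the simplest strictly positive, right-skewed model consistent with the LOS
literature. The DRG reference table is derived from the generating model
itself: the benchmark is the *exact* marginal mean LOS per DRG and the
threshold is the upper quantile at which a configured overall outlier
fraction (default 3.74%) is attained in expectation — mimicking a dynamic
mean benchmark and a fixed regulatory cutoff. Both are computed in closed
form by enumerating the discrete distribution of the summed covariate
effects (about 42,000 atoms), and the noise SD is calibrated by 1-D root
finding so the expected long-stay fraction hits its target (default
40.06%). With all effects zero the long fraction reduces to the closed-form
lognormal exceedance $P(Z > \sigma/2)$, which the tests exploit as an
independent oracle.

Default effect sizes are moderate and clinically plausible (older, urgent,
oncological and septic admissions stay longer; planned admissions shorter).
`config_parameter_recovery()` freezes a separate, well-separated benchmark:
a dominant +2.0 log-scale effect on the cancer indicator at 30% prevalence
over moderate supporting effects and $\sigma = 0.3$, under which the
selection floors are attainable and the dominant covariate should be
recovered as the top Garson contributor with a positive sign.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: covariates are conditionally independent given the
unit (no age-cancer or diagnosis-admission correlation), the DRG is drawn
independently of the diagnosis group, LOS is exactly log-normal with
homogeneous noise, and prevalences are stationary across years. Published
percentage blocks that do not sum to exactly 100 (they are rounded marginals)
are renormalized proportionally.

## Numerical conventions and degenerate inputs

Strict inequality defines both outcomes; ties label 0. A score exactly at
the classification cutoff predicts 1. Single-class training labels, unknown
DRG codes, unknown enum levels (named by row and field), thresholds not
exceeding benchmarks, and zero-weight networks in `garson()` all raise
errors rather than guessing. Bootstrap resamples that come out single-class
are redrawn up to 10 times, then skipped with a warning. All randomness in a
pipeline run flows from one integer seed; reruns are byte-identical
(manifest hashes are compared in the tests).

## Problem sizes used in the shipped studies

The packaged tests and the acceptance script run the parameter-recovery
study at 20 replicates of a 10,000-record cohort with 25 bootstrap
replications, 10 hidden nodes and at most 100 epochs per training — sizes
chosen so the full study completes in a few minutes on a single core while
leaving the floor and recovery margins wide. The published-table identities
(diagnostic indexes and impact arithmetic) are exact recomputations and run
in well under a second.

## Known limitations

* The selection floors are checked in-sample; with few positives (the rare
  outlier outcome) the selected training metrics are optimistic relative to
  validation — the reported evaluation always comes from the untouched
  validation set.
* `auc_binary` is a single-threshold identity, not a score-based ROC area;
  both are reported, but only the former matches the published convention.
* Revenue projections are linear in the supplied tariff table and ignore
  capacity constraints, seasonality and queueing.
* The generator's independence assumptions above; effect recovery results on
  synthetic cohorts bound what the architecture can do, not what real
  administrative data support.
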