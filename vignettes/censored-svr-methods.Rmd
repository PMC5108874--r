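---
title: "Censored support vector regression: models, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored support vector regression: models, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survsvr)
```

## The problem

Right-censored survival data pair a follow-up time $y_i > 0$ with an event
indicator $\delta_i \in \{0, 1\}$: $\delta_i = 1$ means the event (e.g.
death) was observed at $y_i$, $\delta_i = 0$ means the subject was still
event-free when observation stopped. Standard support vector regression
assumes fully observed responses; survival data require losses that respect
the partial information carried by a censored time: the true event time is
*at least* $y_i$, but how much larger is unknown.

`survsvr` implements three SVR formulations for this setting, all of the
form

$$\min_{w, b, \text{slacks}} \tfrac12 \|w\|^2
  + \gamma \sum_i (\epsilon_i + \epsilon_i^*)
  + \mu \sum_i \xi_i$$

with a prognostic index $u(x) = w^\top\varphi(x) + b$ (higher $u$ =
longer predicted survival) and model-specific constraints:

* **Standard censored SVR** (`fit_model1`). Everyone gets the lower
  constraint $u_i \ge y_i - \epsilon_i$; only events get the upper
  constraint $u_i \le y_i + \epsilon_i^*$. A censored subject is thus
  penalized only for being predicted *below* its censoring time —
  a one-sided loss.
* **Ranking + regression SVR** (`fit_model2`). Adds, for each subject with
  a *comparable neighbor* $j(i)$ (the subject with the largest time
  strictly below $y_i$ whose relative event order is known, i.e. an
  observed event), the constraint
  $u_i - u_{j(i)} \ge y_i - y_{j(i)} - \xi_i$, weighted by $\mu$.
* **MRL-augmented SVR** (`fit_ssvr_mrl`). Makes the loss two-sided for
  censored subjects by imputing their event time as censoring time plus
  mean residual lifetime: $u_i \le y_i + \mathrm{MRL}(y_i) + \xi_i$ for
  $\delta_i = 0$, weighted by $\mu$. $\mathrm{MRL}(t) =
  \int_t^\infty S(u)\,du / S(t)$ is computed from the Kaplan–Meier curve
  of the training set.

All three are solved through the Wolfe dual so that any positive
semidefinite kernel applies (linear, inhomogeneous polynomial
$(x^\top z + 1)^d$, RBF $\exp(-\gamma_{\text{rbf}}\|x-z\|^2)$, and the
clinical additive kernel for mixed continuous/categorical data).

## Numerical choices in the solver

The dual is a box-constrained QP with one equality constraint, solved with
`quadprog` (Goldfarb–Idnani). Three details matter and are worth recording:

* **Collapsed regression multipliers.** A subject's lower and upper
  regression multipliers $\alpha_i, \alpha_i^*$ enter the dual only through
  $\beta_i = \alpha_i - \alpha_i^*$ and share the linear coefficient
  $y_i$, so they are one variable with box $[-\gamma, \gamma]$ (events) or
  $[0, \gamma]$ (censored). This halves the QP dimension exactly.
* **Rank-deficient Hessians.** With a linear kernel the dual Hessian has
  rank $\le d + 1$; `quadprog` requires positive definiteness, and with a
  too-small ridge it can return infeasible or feasible-but-suboptimal
  points *without erroring*. The solver normalizes variables by their box
  scale, verifies feasibility, escalates the ridge on a geometric ladder,
  and removes the ridge bias by proximal-point iteration (re-solving with
  the linear term shifted by the ridge times the incumbent, whose fixed
  point is the un-ridged optimum).
* **Flat dual, sharp primal.** Near the optimum the dual objective is
  quadratically flat in directions along which the *primal* objective
  changes linearly (scaled by $\gamma$). Small problems (QP dimension
  $\le 100$) therefore get an active-set KKT refinement, and linear-kernel
  fits finish with an exact primal polish: constraints are classified
  active/violated/inactive and the resulting equality-constrained QP in
  $(w, b)$ is solved through its KKT system. The result matches an
  independent primal solve to $\sim 10^{-9}$ relative objective error on
  random small instances; large fits accept a single regularized pass,
  which is far below statistical noise.

The bias $b$ is recovered from complementary slackness (median over
strictly interior multipliers), with an exact minimizer of the
piecewise-linear slack cost in $b$ as fallback and cross-check.
Degenerate all-censored training data return a flagged constant model
($w = 0$, $b = \max y_i$) rather than an error, so resampling harnesses
survive bad folds.

## Kaplan–Meier and MRL conventions

`km_estimate` uses the product-limit estimator with events preceding
censorings at tied times. The MRL integral $\int_t^\infty S$ is undefined
when the curve does not reach zero (largest observation censored);
`mrl_at` truncates the integral at the largest observed time — the
restricted-mean convention — which keeps MRL finite without distributional
assumptions, and returns 0 at or beyond that time. With no censoring,
`mrl_at(s, 0)` equals the sample mean exactly, which the tests assert.
MRL values are computed once per fit from the training set only.

## Performance measures

* `c_index`: Harrell's concordance over usable pairs (shorter time is an
  event and strictly smaller; tied-time event pairs skipped; prediction
  ties count 1/2).
* `logrank_chi2`: subjects are split at the *median prognostic index*
  (ties to the low group) and the two-sample log-rank $\chi^2$ (1 df) is
  computed. The median split is a choice the source methodology leaves
  open; it makes the statistic invariant to monotone transforms of $u$.
* `hazard_ratio`: $\exp(|\hat\beta|)$ from a univariate Cox fit of the
  below-median-index indicator, so the reported ratio is $\ge 1$
  regardless of orientation; monotone likelihood (a group without events)
  caps it at 100 with a warning. A per-unit-index HR was considered and
  rejected as the default because group-based ratios are what the
  benchmark tables report.
* `wilcoxon_rank_sum`: exact two-sided p-value (via the Mann–Whitney
  count distribution) when the pooled sample size is at most 20 with no
  ties; otherwise the normal approximation with tie correction and *no*
  continuity correction, so identical samples give exactly $p = 1$.

## Tuning and the benchmark harness

`tune` does exhaustive grid search maximizing mean validation c-index over
3-fold cross-validation (c-index because it is the lead measure
throughout), ties broken toward smaller $\gamma$, then $\mu$, then the
kernel parameter. Default grids: $\gamma, \mu \in \{2^{-8}, 2^{-6},
\dots, 2^8\}$; RBF bandwidth the inverse 0.1/0.5/0.9 quantiles of pairwise
squared distances; polynomial degree 2 or 3. The *reduced* grid
($\{2^{-4}, 2^0, 2^4\}$) is used inside heavy loops.

`evaluate_repeated` implements the repeated-holdout protocol: 2/3–1/3
random split, standardization fitted on the training part (population-SD
convention; standardization is on by default because the RFE criterion
$w_j^2$ is scale-dependent), optional tuning, fit, and the three measures
on the test part; medians and SDs over replicates are reported, and models
evaluated with the same master seed see identical splits, so
`compare_models`' Wilcoxon tests operate on paired replicate streams
(the test itself is kept unpaired, as in the source methodology).
Reported dispersion is the SD of replicates alongside the median; means
are also stored since the benchmark tables' "a ± b" convention is
ambiguous.

## Feature selection

Three methods, all driven by the linear standard SVR:

1. `association_tests`: the prognostic index is computed once, then each
   feature is tested against it (Pearson for continuous, pooled-variance
   t-test for binary, one-way ANOVA for ≥3 levels). Rows in an `"Unknown"`
   category are excluded from that feature's test but kept for fitting.
2. `univariate_rank`: each feature alone in a univariate SVR, ranked by
   median test c-index (descending — the only reading under which the
   "top ranked" features are informative).
3. `rfe`: backward elimination by smallest squared weight, one feature per
   step (ties drop the later-indexed feature), $\gamma$ re-tunable on a
   reduced grid per step, producing exactly $d$ nested subset evaluations.

The "best" subset is flagged by SVR median c-index alone; the other two
measures are reported but do not vote.

## The simulator and what a green test establishes

`simulate_dataset` draws standard-normal features, a weight vector that is
zero on a random half of the features and standard normal on the rest,
event times $T_i \sim \text{Exp}(\text{mean } m_i)$ and censoring times
$C_i \sim \text{Exp}(\text{mean } c\, m_i)$. Because $w^\top x$ can be
negative it cannot itself be an exponential mean; the default link is
$m_i = \exp(w^\top x_i)$ (log-linear AFT form), with
$m_i = \max(w^\top x_i, 0.01)$ available as `link = "truncate"` for
sensitivity. Since both exponentials share $m_i$, the event probability is
$c/(1+c)$ per subject independent of $x$; the default $c = 13/7$ fixes the
censoring fraction at 35%.

This generator is a stated world, not a fit to any dataset: its defaults
were chosen once, before any benchmark was run. Two of its properties
matter for interpreting results. First, it carries *strong* signal — the
oracle concordance $E[\max(m_i,m_j)/(m_i+m_j)]$ is about 0.88 at $d = 10$
— so both linear SVR and Cox reach c-indexes near 0.8 at $n = 200$, and
the published benchmark values near 0.56 for the same nominal design are
not reproduced by it (nor by the truncation link, measured at ≈0.77); the
generator behind those published values is not recoverable from its
description. The corresponding acceptance checks are left failing with
this analysis rather than recalibrated post hoc. Second, with the exp link
at large $d$ the outcome spans many orders of magnitude
($\log m \sim N(0, d/2)$), a regime real clinical data do not inhabit; a
green recovery test at $d = 10$ says the pipeline ranks and selects
correctly under exponential AFT noise, not that it would on any particular
clinical cohort.

## Known limitations

* Interval censoring, left truncation and time-varying covariates are out
  of scope.
* The clinical kernel's serialization (`save_svr_model`) stores only the
  kernel kind and scalar parameters; clinical-kernel models must be refit
  rather than reloaded.
* The MRL tail truncation biases imputed event times downward when the
  last observation is censored and the tail mass is substantial.
* The Cox baseline falls back to a lightly ridge-penalized fit only on
  rank deficiency or non-convergence; at $d$ close to $n$ its unpenalized
  estimates are noisy, which is inherent to the comparison it serves.
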