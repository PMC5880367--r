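---
title: "Modeling strategy variability in children's causal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling strategy variability in children's causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(blicketlca)
library(dplyr)
```

## The scientific question

When 2- to 5-year-olds solve blicket-detector tasks — screening-off,
indirect screening-off, backwards blocking — their success rates vary
widely within every age group. Two explanations compete. Children of
different ages may apply *different strategies* (subgroups with
qualitatively different response profiles), or all children may apply *one
strategy* whose *execution accuracy* improves continuously with age. The
two accounts make different predictions about the joint distribution of
success patterns across trials, and that is what this package models.

## The model

Each child $i$ contributes a binary success vector
$y_i = (y_{i1}, \dots, y_{iJ})$ over $J$ test trials and an age $x_i$ in
months. A latent class model with $K$ classes assumes

$$
\Pr(y_i \mid x_i) \;=\; \sum_{c=1}^{K} \pi_c(x_i)
  \prod_{j=1}^{J} p_{cj}(x_i)^{\,y_{ij}}\,
  \bigl(1 - p_{cj}(x_i)\bigr)^{1-y_{ij}},
$$

with trials conditionally independent given class. Three variants differ in
where age enters:

* **No covariate** — $\pi_c$ and $p_{cj}$ are constants. This is the plain
  Bernoulli-mixture LCA.
* **Age on membership** (concomitant-variable model) — class membership
  follows a multinomial logit in age,
  $\pi_c(x) \propto \exp(\alpha_c + \beta_c \tilde{x})$ with class 1 as the
  reference ($\alpha_1 = \beta_1 = 0$), while response probabilities stay
  constant. Strategy *choice* changes with age; strategies themselves do
  not.
* **Age on responses** — each response probability follows a logistic curve
  in age, $\mathrm{logit}\, p_{cj}(x) = \gamma_{cj} + \delta_{cj}\tilde{x}$.
  With $K = 1$ this is the accuracy-growth account: one strategy, executed
  better with age.

The links are not prescribed by the data themselves; the multinomial logit
for membership and the logistic link for responses are the standard
concomitant-variable forms, and we adopt them. $\tilde{x}$ is age
standardized by the sample mean and SD — purely a numerical-conditioning
device; `tidy()` reports slopes back on the per-month scale.

## Fitting

`fit_lcm()` maximizes the log-likelihood by EM. The E step computes
responsibilities by Bayes' rule; the M step is closed-form
(posterior-weighted means) without covariates, a damped-Newton weighted
multinomial logit for the membership model, and per-cell posterior-weighted
logistic regressions for the response model. Numerical choices that
matter:

* **Restarts.** EM only finds local optima, so the default is 20 random
  starts: response probabilities from uniform(0.2, 0.8), class weights from
  a symmetric Dirichlet, covariate slopes at zero. One master seed derives
  per-restart sub-seeds, so every fit is exactly reproducible. Covariate
  fits screen all starts with short EM runs and continue the three most
  promising ones to convergence (the usual emEM device); covariate-free
  fits are cheap enough to run every start to convergence.
* **Convergence.** A run stops when the log-likelihood increase drops below
  `tol = 1e-8`. The iteration cap is 5000 by default: runs whose estimates
  approach the boundary of the parameter space gain likelihood
  geometrically slowly, and a cap of a few hundred would routinely bite.
  Covariate-free models make the cap cheap to afford — their likelihood
  depends on the data only through the $2^J$ response-pattern counts, so EM
  runs on the collapsed table regardless of $n$. The four-step pipeline
  raises the cap to 50000 because it insists on actual convergence even for
  deliberately overfit candidate models, which approach their optimum along
  a flat ridge.
* **Clipping.** Inside likelihood evaluation response probabilities are
  floored at $10^{-10}$ from 0 and 1; stored estimates are never clipped,
  so boundary counting (below) sees exact 0/1 values.
* **Label order.** Classes are relabeled by decreasing size (at the mean
  age) after fitting, so "class 1" is always the largest group. Modal
  assignment breaks posterior ties toward the lower class index.
* **Degenerate classes.** A class whose total responsibility falls below
  $10^{-8}$ keeps its previous response parameters and is flagged rather
  than producing 0/0.

## Boundary-adjusted model selection

Estimated response probabilities frequently land exactly on 0 or 1. A
parameter at the boundary of its space does not contribute a direction of
variation, so it is excluded from the penalty dimension: the effective
count is the number of freely estimated parameters minus the number
estimated at the boundary (`lcm_effective_params()`), and BIC/AIC use that
count. The boundary tolerance is $10^{-3}$: at the two-decimal precision at
which response probabilities are read, anything within 0.001 of 0 or 1 is
a boundary estimate, while genuine interior estimates stay clear of it. An
empty class additionally surrenders its whole row of response parameters.
Non-nested models (different $K$) are compared by BIC with ties broken
toward fewer classes; AIC is computed and reported but never drives the
selection. Nested models (same $K$, covariate added) are compared by the
likelihood-ratio test with df equal to the number of covariate coefficients
freed — $K-1$ for membership, $K \times J$ for responses — taken from the
model structure, not from the boundary-adjusted counts, which could
otherwise produce a negative df when a class empties.

## Goodness of fit

`lcm_g2()` compares observed counts of the $2^J$ response patterns with
their expected counts under the fitted model, $G^2 = 2\sum O_s \log(O_s /
E_s)$. Under a covariate model the expected counts marginalize over the
empirical age distribution ($E_s = \sum_i \Pr(s \mid x_i)$); nothing in the
model says how else a continuous covariate should enter a pattern table.
The nominal df, $(2^J - 1)$ minus the effective parameter count, is floored
at zero with a warning. With $n = 90$ children spread over 16 cells many
cells are empty or tiny, and the chi-square approximation to $G^2$ is not
trustworthy; the operative fit measure is the parametric bootstrap
(`lcm_bootstrap_gof()`): simulate $B$ replicate datasets from the fitted
model keeping each child's observed age, refit the same specification with
the same restart policy, and count how often the replicate $G^2$ reaches
the observed one. The add-one rule $(1 + \#\{G^2_b \ge G^2_{obs}\})/(B+1)$
keeps the p-value away from exact zero, so $p \ge 1/(B+1)$ always; a
replicate whose refit fails to converge is redrawn with a fresh sub-seed
and the redraws are logged.

## What the generator emulates — and what it does not

`simulate_lcm_data()` exists so that every stage of the pipeline can be
exercised without access to child-level data. The `"study"` preset encodes
the three-strategy world the analysis is built around: class proportions
51/90, 27/90 and 12/90; response probabilities (1, .67, .94, 1),
(.48, .33, 1, 0) and (0, 0, 1, 1) over the four retained trials; and group
sizes 23/23/23/21 with ages drawn per group from normal distributions —
means 30.04, 40.87, 54.39, 67.33 months, SDs 3.16, 3.56, 2.98, 2.44 —
truncated to each group's 12-month band so that group labels and ages never
disagree. Truncation is our choice; only means and SDs are given by the
design, and the truncated normal is the simplest family consistent with the
group bands.

The `"age_logit"` preset replaces fixed proportions with a multinomial
logit in age, calibrated so the first-class share rises with age, the
second-class share falls (modal class 2 among 2-year-olds, modal class 1
from age 3 on), and the third class stays small throughout — intercepts
(4.32, -2.2) and slopes (-0.12, 0) per month against class 1. This is a
calibration device for testing discrimination between the age-on-membership
and accuracy-growth accounts, not a reconstruction of any fitted
coefficient: the published analysis reports no age-to-class equation, and
percentages read off a figure are not treated as ground truth. The
`"one_class"` and `"accuracy_growth"` presets supply the null worlds the
pipeline must *not* mistake for strategy variability.

What passing tests on these simulations show is that the machinery —
selection, covariate testing, recovery, calibration — behaves correctly
when the model family is true. Real children need not oblige: trials may
not be conditionally independent given strategy (fatigue, carry-over),
strategies may not be exhaustive, and the age-to-membership relation need
not be logit-linear. Results on synthetic data bound what the method can
do, not what any particular dataset will show.

## The four-step pipeline

`run_variability_analysis()` chains the analysis exactly as a strategy
study would run it:

1. fit $K = 1, \dots, 4$ classes without covariates and select $K^*$ by
   lowest BIC;
2. extend the $K^*$ model with age on membership (on responses when
   $K^* = 1$, the only extension a one-class model admits) and test the
   extension by LRT;
3. fit the one-class accuracy-growth model and compare BICs;
4. report the selected model's response-probability table, its $G^2$ with
   bootstrap p, modal classifications, and the strategy-by-age-group
   percentages.

Step 2's covariate placement for $K^* = 1$ is our resolution of a corner
the four-step recipe leaves open (a membership covariate needs at least two
classes to act on); it keeps the step meaningful as "does age explain
anything beyond the selected structure?".

## Scoring and screening

`score_responses()` maps raw trial codes to binary success: placing the
causally efficacious object X alone (screening-off), object Z alone
(indirect screening-off A), labeling Y a blicket (indirect screening-off
B), *not* labeling Y a blicket (backwards blocking), and using a finger
press (non-causal association). Every other scorable response is a failure;
unscorable codes exclude the child listwise. Success on the B trial depends
only on the label given to Y — an optional strict mode additionally
requires X to be labeled correctly, off by default since the standard
definition scores the target object only. `screen_item_variability()`
drops items whose overall success proportion falls below 0.05; the screen
is deliberately one-sided, since a near-ceiling item (97% success) still
separates the all-boundary strategy from the rest, whereas a floor item
(2% success) separates nothing.

For cross-study 2x2 comparisons, `chisq_2x2()` is the classical
uncorrected Pearson statistic — the continuity-corrected version does not
reproduce standard printed comparison values — and `fisher_2x2()` sums
hypergeometric probabilities of tables no more probable than the observed
one (the common software convention), with a doubling convention available
because published exact p-values are sometimes computed that way.

## Problem sizes used in the checks

The packaged checks run the selection experiment on 20 simulated studies of
$n = 500$, the recovery experiment on 50 studies of $n = 2000$, and the
bootstrap-calibration experiment on 100 replicate studies with $B = 99$
using a well-separated two-class, four-trial model at $n = 60$ (strong
separation keeps each of the ~10,000 EM refits to a few dozen iterations
while leaving the calibration property intact). These sizes give the
stochastic quantities comfortable margins: e.g. the recovery means carry
Monte Carlo standard errors well below 0.01.

## Known limitations

* Items are binary; no ordinal or polytomous responses.
* With four items a three-class Bernoulli mixture sits below the classical
  identifiability threshold (J >= 2K - 1 items), so distinct parameter
  configurations can fit the pattern table equally well. Boundary structure
  restores much of the practical identifiability here, but recovered
  interior probabilities can carry a small systematic offset (about 0.02 in
  the packaged recovery experiment) that no amount of data removes.
* One measurement occasion; no latent-transition extension.
* The bootstrap refits inherit the restart policy of the original fit; a
  policy with very few restarts can let replicate fits land in local
  optima and bias the null distribution of $G^2$ upward.
* With boundary-heavy solutions the nominal $G^2$ df is a bookkeeping
  quantity only; conclusions about absolute fit should rest on the
  bootstrap p.
* Class labels are descriptive ("largest class" first); any cognitive
  interpretation of a class profile lives outside the model.
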