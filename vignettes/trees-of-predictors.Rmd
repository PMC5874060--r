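---
title: "Trees of predictors for fixed-horizon survival risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trees of predictors for fixed-horizon survival risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topsurv)
```

## The problem and the model

Clinical cohorts — the motivating example is survival of heart-transplant
candidates and recipients — are rarely homogeneous: different subpopulations
carry different risk factors, and a single global model averages those
differences away. `topsurv` addresses fixed-horizon survival prediction
(will this subject die within 3 months, 1, 3, 10 years?) with a *tree of
predictors*: a recursive partition of covariate space in which every node
(cluster) carries its own fitted risk model, and a subject's prediction is a
weighted average of the models along their root-to-terminal path,

$$H(x) = \sum_{C \in \Pi(x)} w(C, \Pi)\, h_C(x),$$

where $\Pi(x)$ is the unique root path of the terminal cluster containing
$x$, $h_C$ is cluster $C$'s model and the weights $w$ lie on the simplex.

The construction is greedy and validation-driven. The development set is
split once into a training part and a validation part (stratified 80/20 by
default). Stage 0 trains every learner of the base class — Cox proportional
hazards, a least-squares linear probability model, and a lightly
L2-regularized logistic regression — on the training part and assigns the
one with the highest validation AUC to the root. Each later stage considers,
for every terminal cluster $C$, the joint grid of

* a feature $i$ and a threshold $\tau$ (per-node deciles of the feature
  over $C$'s training members), splitting $C$ into
  $C^- = \{x_i < \tau\}$ and $C^+ = \{x_i \ge \tau\}$;
* a learner for each side; and
* a *training node* for each side, drawn from $C$'s root path or the
  prospective child itself — so a small child may borrow the statistical
  strength of a larger ancestor cluster while still being scored only on its
  own region.

The candidate's score is the AUC of the combined two-sided scorer on $C$'s
validation members; the best candidate is accepted only if it beats the
incumbent $h_C$ by more than $\varepsilon$. Construction stops when no
terminal admits an improving split, which — together with child-size floors
and a depth cap — guarantees termination. Finally, per-terminal path weights
are fitted by non-negative least squares of validation labels on the path
models' scores, normalized to sum to one.

Binary classification at a horizon $h$ requires censoring-aware labels: a
subject censored before $h$ has unknown status at $h$ and is excluded from
binary training and AUC evaluation; everyone else is labelled by whether
death occurred within $h$. The Cox learner is the exception: it trains on
follow-up times and event indicators of all subjects in its cluster,
censored included, and converts to a horizon risk through the Breslow
baseline, $1 - \hat S_0(h)^{\exp(\beta^\top x)}$. Throughout the package
the positive class is death within the horizon; reported AUCs are
orientation-symmetric so survival- and mortality-phrased statements agree.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `validation_fraction` | 0.2 | proportion | one stratified split fixed before construction; all selection AUCs use only the validation part |
| `quantile_count` | 10 | bins | candidate thresholds are interior deciles per node, de-duplicated; discretization of continuous features |
| `min_child_training_size` | 50 | subjects | below this, node models are too noisy to be worth a split |
| `min_child_validation_per_class` | 5 | subjects | keeps child validation AUCs defined and stable |
| `improvement_epsilon` | 1e-4 | AUC | "no further improvement" tolerance for the stopping rule |
| `max_depth` | 10 | levels | a safety cap; discovered trees are typically much shallower |
| horizons | 91, 365, 1095, 3650 | days | 3 months, 1, 3, 10 years at 365 d/yr |

Two readings of the construction needed a decision. First, "weakly
preceding" training nodes are taken to be the root path *plus the
prospective child itself* — exactly the clusters whose regions contain the
child's region. Second, the acceptance gate is node-local (candidate AUC vs
the incumbent's on the same validation members), but an accepted stage must
also not decrease the overall tree validation AUC on the full validation
set; node-local gains are not mathematically guaranteed to compose, and the
extra guard (which rarely binds) makes the build log's overall-AUC column
non-decreasing by construction. When several terminals admit improving
splits, one split is accepted per stage: the one with the largest node-local
improvement, ties broken by node creation order; within a node's grid, ties
break by lower feature index, smaller threshold, learner order
COX < LINEAR < LOGISTIC (left side then right), then shallower training
node.

The path weights are fitted by non-negative least squares rather than
unconstrained regression because simplex weights guarantee $H(x) \in [0,1]$
for free; collinear path scores and terminals with fewer than 10 validation
members fall back to uniform weights. "Linear perceptron" is implemented as
the least-squares linear probability model with output clipped to $[0,1]$:
it is deterministic, convex, and serves both as a base learner and as the
historical name for fitting a linear scorer. The logistic learner carries a
small fixed ridge penalty ($\lambda = 10^{-4}$ on standardized columns,
intercept unpenalized) purely so the IRLS solve stays well-posed on small or
separable clusters. Features are standardized per training subset inside
each learner (binary columns untouched) and the transform is frozen into
the fitted model.

## Preprocessing

Features with more than 10% missing entries are dropped (strictly greater:
exactly 10% is retained). Categorical features with $k > 2$ levels become
$k$ one-vs-rest indicators — deliberately redundant, which is harmless for
regularized or rank-based downstream use and keeps every indicator
interpretable on its own. Missing entries are filled by column mean
(continuous) or mode (binary), with fill values learned on the development
cohort and frozen for held-out scoring; the `strategy` enum is the hook for
richer imputers, and the deterministic single-pass choice keeps stochastic
imputation variance out of the algorithmic test surface. Per-cluster
feature relevance is the absolute Pearson correlation between each encoded
column and the horizon label; the three most relevant features per node are
part of the tree description, which is the method's interpretability story.

## Metrics

`auc` is the tie-aware Mann-Whitney estimator (half credit for ties).
`concordance_index` is Harrell's C with the classical conventions: pairs
are comparable when the shorter time carries an event (censored subjects
participate as the longer member), score ties get half credit, and
equal-time double-event pairs count as comparable with half credit.
Calibration bins subjects into equal-frequency score deciles (duplicate
boundaries merged) with normal-approximation 95% binomial intervals, and
$\rho$ is the RMSE of the calibration points around the identity line.
`sensitivity_at_specificity` returns the smallest threshold whose
specificity reaches the target plus raw correct-positive/negative counts;
a mirrored `specificity_at_sensitivity` is provided. Cross-validation
reports mean ± SD across folds per horizon, with the discard rule applied
to AUC but never to the C-index; era-restricted evaluation (train on one
calendar window, test on a later one) replaces the fold loop when date
bounds are supplied.

## The synthetic cohort generator

Because the motivating registry data are access-restricted, the package
ships a generator that emulates their statistical structure: covariates are
standard normal (continuous) or Bernoulli(0.5) (binary); an ordered list of
planted (feature, threshold) rules defines up to $2^k$ clusters; each
cluster has its own coefficient vector $\beta_k$ and baseline rate
$\lambda_k$ (events/year), with event times exponential (or Weibull) with
rate $\lambda_k e^{\beta_k^\top x}$ and independent uniform censoring. The
closed-form risk $1 - \exp(-\lambda_k e^{\beta_k^\top x} h)$ is returned as
an oracle, so calibration and recovery tests have exact ground truth.

Three canonical scenarios fix the study conditions used by the tests:
`homogeneous` (n = 4000, one population — nothing to discover, exercising
the stopping rule), `single_split` (n = 4000, two subpopulations at
$x_1 = 0$ with opposing coefficient vectors and no marginal $x_1$ effect, so
the split is identifiable but invisible to a global linear model), and
`four_cluster` (n = 8000, nested thresholds on $x_1$ and $x_2$ with
sign-flipped within-cluster effects that cancel globally and
cluster-specific baseline rates 0.30–0.55/yr). Rates and effect sizes were
chosen once to give moderate 1-year label prevalence (roughly 0.25–0.4) and
censoring in the realistic 10–30% range under a 10-year uniform censoring
bound. These cohorts deliberately do *not* reproduce registry marginals,
era effects, informative censoring or missing-data patterns, so passing
tests demonstrate algorithmic correctness and the heterogeneity advantage
under ignorable censoring — not clinical performance.

## Numerical choices and degenerate inputs

Candidate thresholds equal to a side's minimum simply produce an
inadmissible empty child and are skipped by the size floors. Nodes whose
validation members carry a single label, or with fewer than twice the
child-size floor of training members, decline to split. Learner fits that
fail (degenerate labels, non-convergence) silently remove that candidate
from the grid; at the root, at least one learner must fit or construction
errors. Constant columns receive zero coefficients exactly. Survival curves
across horizons are made monotone by pool-adjacent-violators before linear
interpolation, with $S(0) = 1$ anchored.

A note on problem sizes: the shipped scenarios (n = 4000–8000, six
covariates, deciles) build in seconds to tens of seconds; they were sized so
that split recovery and the heterogeneity advantage are statistically
unambiguous across seeds while the full property suite stays comfortably
runnable on a laptop.

## Known limitations

* The split search is greedy; a split that only pays off two levels deeper
  is never found.
* Split candidates are selected *and* acceptance-gated on the same
  validation members, so on truly homogeneous data the maximum over the
  large candidate grid exceeds the incumbent by chance and some spurious
  splits are accepted; path weighting keeps the held-out cost small (on the
  homogeneous scenario, within about 0.01 AUC of the global logistic
  model), but root-only trees should not be expected.
* Single imputation understates uncertainty relative to multiple
  imputation; the strategy hook exists but only mean/mode ships.
* No competing risks, no informative censoring, no surrogate splits for
  missing values at prediction time (imputation handles them instead).
* The C-index is reported per horizon (plus the across-horizon mean); a
  truly time-dependent concordance is out of scope.

## A worked example

```{r example, eval = FALSE}
sc <- generate_cohort(scenario_config("four_cluster", n = 8000, seed = 1))
fit <- tops_fit(sc$cohort, horizons = c(365, 1095),
                config = build_config(seed = 2))
print(fit)
describe_tree(fit$trees[["365"]])

new <- generate_cohort(scenario_config("four_cluster", n = 2000, seed = 99))
risk <- tops_score(fit, new$cohort)
task <- make_horizon_labels(new$cohort, 365)
auc(risk[task$included, "365"], task$label[task$included])
```
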