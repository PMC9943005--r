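---
title: "Prognostic modelling of right-censored EHR cohorts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic modelling of right-censored EHR cohorts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

`phnnsurv` builds prognostic models for a right-censored time-to-event
outcome — the motivating application is incident heart failure in a cohort of
diabetic outpatients followed through electronic health records — from a
baseline table of mixed continuous and binary covariates with missing values.
Both model families assume proportional hazards,

$$h(t \mid X) = h_0(t)\, r(X),$$

and differ only in how the relative hazard $r(X)$ is parametrized:

* **Penalized linear Cox (COX).** $r(X) = \exp(\beta \cdot X)$, with $\beta$
  estimated by maximizing the elastic-net-penalized partial likelihood. The
  penalty weight $\lambda$ is chosen by 10-fold cross-validation with the
  one-standard-error rule: the *largest* $\lambda$ whose CV error is within
  one standard error of the minimum, which favors the most parsimonious
  model statistically indistinguishable from the best one.
* **Proportional-hazards neural network (PHNN).** $r(X) = \exp(f_\theta(X))$,
  where $f_\theta$ is a feed-forward network — by default four hidden layers
  of 128, 64, 32 and 15 rectified-linear units with activation dropout 0.5
  after every hidden layer — trained by minimizing the negative Breslow
  partial likelihood with early stopping on a validation set.

Both families share one contract (`predict_log_hazard()` plus a Breslow
baseline cumulative hazard), so absolute risk at a horizon,
$1 - S(t\mid X) = 1 - \exp(-\hat H_0(t) e^{f(X)})$, forward feature
selection, partial-dependence explanations and the whole validation suite
apply to either interchangeably.

## Preprocessing, bound to model family

The two families get the preprocessing that suits their estimators:

* **COX path**: chained-equation imputation (iterative per-covariate
  regressions — linear for continuous, logistic for binary — cycled 10
  times from mean initialization). A *single* completed dataset is produced;
  multiple-imputation pooling is deliberately out of scope because a single
  coefficient vector is the deliverable. Covariates stay on their natural
  scale; the penalized solver standardizes internally.
* **PHNN path**: mean imputation plus a binary `<name>_missing` flag per
  covariate with training missingness (so the network can exploit
  informativeness of *being measured*), followed by quantile normalization
  of continuous covariates to a standard normal (1000 empirical quantile
  knots, linear interpolation, out-of-range values clipped to the extreme
  training quantiles). Flags and binary covariates pass through untouched.

Every preprocessing state is fitted on training rows only and applied
unchanged to validation and test rows; the imputers are idempotent on
completed data. The quantile map is a one-shot coordinate change — composing
it with itself is *not* the identity, so the pipeline applies it exactly
once. The split itself is event-stratified (70/15/15 by default, largest
remainder apportionment within each stratum), keeping the event fraction of
every partition within a percentage point of the cohort's at realistic sizes.

## Training the network

The partial likelihood couples all subjects through risk sets, so the loss
is computed **full batch**: one Adam step per epoch over the entire training
set, with the analytic gradient of the event-averaged negative Breslow
partial likelihood propagated through the network. This avoids the bias
minibatching introduces into risk-set sums and is exact at the cohort sizes
the package targets ($n \lesssim 10^5$). Consequences for the defaults: the
learning rate (0.02) is larger and the epoch budget (1000, patience 100)
longer than minibatch conventions, because an "epoch" here is a single
gradient step. Dropout is applied after each hidden activation only — never
on the input — and disabled at inference, so predictions are deterministic.
Training rows are internally sorted into a canonical order (time, event,
covariates) before any random draw, which makes the fit exactly invariant
to the row order of the input. Weight initialization and the per-epoch
dropout masks derive from one required seed.

Two degenerate configurations are useful checks rather than use cases: with
no hidden layers and no dropout the network is a linear Cox model and its
trained loss reaches the `coxph()` optimum (the test suite requires
agreement within 1%), and with all-equal scores the loss equals the null
partial likelihood exactly.

## Forward selection

Greedy forward selection adds, at each step, the candidate covariate whose
addition maximizes the validation Harrell c-index, with ties broken by
alphabetical name. "No substantial improvement" is quantified as a gain
below `min_gain = 0.002` over the running best for `patience_steps = 2`
consecutive steps (`max_features = 25` as a hard cap); the defaults
reproduce a ~20-feature scale on cohorts like the default generator's, but
all three are configuration, not science. During selection the per-candidate
model may be a reduced-epoch network, since only the *ranking* of candidates
matters; the final model is refitted in full on the chosen set. Selection
sees training and validation rows only.

## Validation suite

* **Harrell c-index**: concordant pairs plus half the score-tied pairs over
  comparable pairs ($t_i < t_j$, subject $i$ an event). Mean and standard
  error come from event-stratified 10-fold cross-validation
  ($\mathrm{SE} = \mathrm{sd}/\sqrt{k}$).
* **Time-dependent AUC** at 24 and 60 months: cumulative-cases /
  dynamic-controls with inverse-probability-of-censoring weights from a
  Kaplan-Meier estimate of the censoring distribution ($1/G(T_i^-)$ for
  cases, $1/G(\tau)$ for controls). Confidence intervals are seeded
  percentile bootstraps; two models are compared by a paired bootstrap of
  the AUC difference with a normal-approximation p-value. The bootstrap was
  chosen over analytic influence-function variance because it is
  assumption-light and directly testable.
* **Calibration**: decile plots (observed risk = within-decile Kaplan-Meier
  at the horizon, which stays valid for subjects censored before the
  horizon under independent censoring) and the integrated calibration index
  (ICI). The ICI smooths observed risk by a proportional-hazards regression
  on a natural cubic spline (3 df) of $\log(-\log(1-p))$ of the predicted
  risk and reports the subject-wise mean absolute gap — averaging over
  subjects realizes the weighting by the empirical density of predictions.
  If the spline fit degenerates, a binned-KM local-regression smoother takes
  over with a logged warning; an all-constant prediction vector reduces to
  calibration-in-the-large against the overall KM estimate.
* **Threshold metrics**: sensitivity, specificity, PPV and NPV at the
  cut-off maximizing Youden's index, after reducing the outcome to a binary
  horizon status. Subjects censored before the horizon are *excluded* there
  (their binary status is undefined) — unlike the calibration deciles, where
  KM handles them; both conventions are intentional and logged.
* **Kaplan-Meier / Aalen-Johansen**: the cumulative-incidence check with a
  competing event reduces exactly to $1-\mathrm{KM}$ when no competing
  events exist; competing-risk *modelling* is deliberately not pursued
  beyond this diagnostic.

## The synthetic cohort generator

No real cohort ships with the package; the generator exists so that every
stage is testable against a known truth. It emulates the statistical
structure of a diabetic EHR cohort: ~30 covariates whose marginals follow
published cohort descriptives (age ≈ 72 ± 11 y, BMI ≈ 28.7 kg/m²,
lab panels, comorbidity and therapy prevalences), a Gaussian copula with a
modest 0.2 correlation block among laboratory values (only marginals are
published; the block is a realism choice), MCAR missingness of 0.10–0.30 on
labs and echocardiographic features and none on age/sex/administrative
flags, and a Weibull baseline (shape 1.3, scale 1150 months) with
administrative censoring (horizon 102 months, uniform 60-month entry
window). Event times are drawn by exact inverse transform of the Weibull
cumulative hazard scaled by $e^{f^*(X)}$ — no discretization — and
missingness is applied after outcomes, keeping it outcome-independent.

The true log-hazard mixes linear terms (age, GFR, left-atrium area), steps
(comorbidities and therapies) and U-shaped terms
$g(x) = c\,(x-x_0)^2$ for hemoglobin and glycated hemoglobin, reflecting the
well-known U-shaped risk of those measurements. Shape/scale and effect
magnitudes were calibrated once so the defaults reproduce the target regime
— ≈17% event fraction over a ≈65-month median follow-up with a
ground-truth discrimination ceiling (c-index of $f^*$) of ≈0.77 — and then
frozen.

What the generator does **not** emulate: visit-level longitudinal structure,
coding artifacts of real EHRs, informative (outcome-dependent) missingness,
measurement error, and competing mortality. Tests passing on this generator
therefore demonstrate correctness of the estimators and the claimed
qualitative orderings (e.g. the network's advantage under non-linear truth),
not clinical transportability.

## Numerical choices and degenerate inputs

* Breslow tie handling everywhere (partial likelihood, baseline, gradient);
  Efron ties, time-varying covariates and stratified baselines are
  non-goals.
* The elastic-net parametrization is
  $\lambda[(1-\alpha)\|\beta\|_2^2/2 + \alpha\|\beta\|_1]$ with
  $\alpha = 0.5$ by default and $\lambda$ scanned on a 100-point log grid
  down to $10^{-3}\lambda_{\max}$; the published description of the original
  analysis does not pin the parametrization uniquely, so both the mixing
  ratio and the grid are exposed.
* Partial-likelihood evaluations center scores before exponentiation
  (shift-invariance makes this free) to avoid overflow.
* Baseline cumulative hazards queried beyond the last observed time return
  the last value with a logged note; $t = 0$ always returns survival 1.
* Constant columns: the quantile normalizer maps them to zeros with a
  warning; rank-deficient chained-equation regressions fall back to mean
  imputation with a warning; folds without events are re-drawn from a
  derived seed with a message.
* Partial dependence clamps a covariate's missingness flag to 0 while
  profiling it — the curve answers "what if this value had been observed" —
  and uses a 20-point grid between the 1st and 99th percentiles
  (continuous) or $\{0,1\}$ (binary).
* One global seed fans out to per-stage derived seeds (hash of the stage
  name) so any stage can be reproduced in isolation.

## Problem sizes used by the checks

The test suite exercises exact oracles on ≤10-row instances; parameter
recovery and the linear-equivalence check on $n = 3000$ cohorts with 5
covariates; the non-linear-advantage and explainability checks on $n = 3000$
with a dominant quadratic effect; calibration oracles on $n = 10{,}000$; and
selection properties on 20 seeded replicates of $n = 400$ (signal ranking)
and one $n = 6000$ cohort (noise termination, where chance concordance gains
sit safely below `min_gain`). The acceptance script runs the full two-model
pipeline on one $n = 10{,}614$ generated cohort. These sizes are the
package's choices for stable Monte-Carlo margins at desk scale.

## Known limitations

* Single-imputation chained equations (no Rubin pooling); uncertainty from
  imputation is not propagated.
* The network reports no uncertainty beyond what the validation suite
  measures; no hyperparameter search is built in.
* Partial dependence is one-dimensional; interaction surfaces are out of
  scope.
* Competing mortality is checked descriptively (Aalen-Johansen vs
  $1-\mathrm{KM}$) but not modelled.
* All discrimination/calibration estimates inherit the independent-censoring
  assumption of KM-based weighting.
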