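---
title: "Physics-informed crop recommendation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed crop recommendation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`agripinn` classifies crop suitability from seven agronomic measurements
(N, P, K in kg/ha; temperature in °C; relative humidity in %; soil pH;
rainfall in mm). Its distinguishing component is a *physics-informed*
classifier: a neural network whose training loss penalises probability mass
placed on crops whose known temperature/pH optima are far from the observed
conditions. This vignette documents the model, its assumptions, the tunable
parameters, the synthetic-data generator, and the design decisions taken
where the method description left the design open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The agronomic knowledge base

Each crop `c` is described by four parameters: `mu_temp`/`sigma_temp`
(mean and spread of ideal temperature, °C) and `mu_ph`/`sigma_ph` (ideal soil
pH). Suitability is scored by an unnormalised Gaussian membership function

$$s(x) = \exp\!\left(-\frac{(x-\mu)^2}{2\sigma^2}\right) \in (0, 1],$$

equal to 1 exactly at the optimum and symmetric in the deviation. The joint
suitability of crop `c` for a sample is the product of its temperature and pH
scores. Two constraints only — temperature and pH — are modelled; the schema
is extensible but constraints on N, P, K, humidity or rainfall are
deliberately out of scope.

**Units.** Scores are always computed on raw physical values, never on
scaled features: the parameters are stated in °C and pH units, and the
expression `T − mu_temp` only type-checks in those units. The training
pipeline therefore carries raw temperature/pH alongside the scaled feature
matrix.

**Provenance of the shipped table.** Published per-crop optima for the
22-crop benchmark schema exist only as figures, not machine-readable numbers.
The shipped `inst/extdata/default_crop_kb.json` is therefore *illustrative*,
written from general agronomic ranges, and flagged as such; analyses should
supply their own table (JSON or CSV, five columns). Every report records the
knowledge-base hash so runs are attributable to a specific table. Whether σ
should differ per crop is unknown from the source material; the package
treats it as free per-crop data.

**Coverage.** Training a physics-informed model on labels absent from the
knowledge base is refused. An explicit `allow_uncovered = TRUE` enables a
neutral fallback (suitability 1, i.e. no penalty). It is off by default
because silently unpenalised classes would fake physics coverage.

## The physics-informed network

A three-linear-layer ReLU network (default widths 7 → 64 → 64 → C) with
softmax output is trained by mini-batch Adam on

$$L_{total} = L_{data} + \lambda_{physics}\, L_{physics},$$

with multiclass cross-entropy $L_{data}$ (probabilities clipped to
$[10^{-12}, 1]$ before the log — numerical safety with no effect above the
clip) and, per sample `i` and crop `c`,

$$\mathrm{penalty}_{ic} = 1 - p_{ic}\, s^{temp}_c(T_i)\, s^{pH}_c(pH_i).$$

**Aggregation (open design point).** The source method defines the penalty
"for a single crop" and computes it for each sample and crop but never states
the reduction. Default: mean over crops, then mean over samples. This keeps
$L_{physics} \in [0,1]$ for any probabilities and makes $\lambda$ comparable
across class counts. The alternative — penalising only the true class — is
implemented as `physics_mode = "true_class"`; neither is asserted as the
original intent. Under the default, for fixed probabilities the gradient with
respect to $p_{ic}$ is $-s_{ic}/(nC)$: steepest descent raises the
probability of the crops most suitable for the sample, which is the intended
"physics pull" (asserted by finite differences in the tests).

**Unreported training details, chosen once.** $\lambda_{physics}$ is not
reported in the source; default 0.1, exposed as a tunable. Architecture,
epochs (200), learning rate ($10^{-3}$), batch size (32) and the optimiser
(Adam) are likewise unreported and set to ordinary values for a small tabular
MLP; all are configurable. Initialisation is He-scaled Gaussian, seeded;
shuffling is seeded; training is fully deterministic given the config.

**Degeneracy contract.** With $\lambda = 0$ the physics gradient is skipped
entirely, so a $\lambda = 0$ run and a knowledge-base-free run consume the
identical random stream and produce bit-identical weights. This is an
acceptance criterion, not an accident of implementation.

**Divergence.** A non-finite epoch loss aborts with the epoch index. The
per-epoch loss breakdown (data, physics, λ, total — with total = data +
λ·physics checked to 1e−10) is retained on the fitted object.

## Tree-based base learners

The target environment ships no tree-model package, so CART-style learners
are implemented in compiled code within the package:

* **Random forest** — bagged gini trees with per-node random feature subsets
  (`mtry = floor(sqrt(p))`). Defaults from the tuned values reported for this
  task: 116 trees, depth 16, `min_samples_split` 10.
* **Extra-trees** — no bootstrap; one uniformly random threshold per
  candidate feature, best candidate by gini. Defaults: 441 trees, depth 16,
  `min_samples_split` 5.
* **Gradient boosting** — second-order boosting with a softmax objective:
  per round, one regression tree per class is fitted to the gradient/hessian
  of the multiclass log-loss, with leaf values $-G/(H+\lambda_{reg})$ scaled
  by the learning rate, and optional row subsampling. Defaults: 465 rounds,
  learning rate 0.064, depth 7 (the tuned values reported for this task).

Ties at identical feature values are never split between; thresholds are
midpoints of adjacent distinct values; single-class or sub-`min_samples`
nodes become leaves holding class proportions.

## Stacking

The stacking construction is not specified in the source beyond base/meta
roles; the package uses the standard leakage-free recipe: out-of-fold class
probabilities under a stratified 5-fold plan (seed 42) form an
$n \times (B \cdot C)$ meta-feature matrix — no base ever predicts a row it
was trained on — and an L2-regularised multinomial logistic regression
(glmnet, `alpha = 0`, fixed small ridge penalty) is fitted on it. Bases are
refitted on the full training set for inference. Meta-features are
probabilities rather than hard labels because the logistic meta-learner
benefits from calibrated inputs; a `hard_labels` switch exists for ablation.
Raw features are not passed through to the meta-learner, matching the minimal
"predictions consolidated by a meta-learner" description. The physics-free
stacking variant is obtained by omitting the PINN base (or setting its
λ to 0), not by separate code.

## Evaluation protocol

* **Split.** Stratified 80/20 train/test, seed 42. Scalers are fitted on
  training partitions only — per split and per CV fold — the conservative
  reading of a description that does not say when scaling happens. pH is
  scaled with the other six features for the network input (uniform input
  scale aids optimisation; the physics loss sees raw values regardless).
* **Folds.** Stratified k-fold (k = 5) by round-robin dealing of seeded
  per-class shuffles, giving per-class fold counts that differ by at most 1.
* **Metrics.** Accuracy = trace/total of the confusion matrix; precision and
  recall are computed one-vs-rest per class and macro-averaged (classes are
  balanced in the target schema, making macro ≈ weighted; a `weighted`
  switch exists). Zero-denominator classes contribute 0 with a warning.
* **Dispersion.** Mean ± *population* standard deviation (ddof = 0) over
  folds, recorded in the report metadata; the per-fold list ships with every
  report so either convention is recomputable.
* Both the CV estimate (primary) and the held-out-20% evaluation (secondary)
  are supported and labelled distinctly. No statistical model comparison is
  performed; reports are descriptive.

## Hyperparameter search

Three strategies behind one interface: **grid** (full Cartesian product of
finite domains; continuous domains are an error), **random** (i.i.d. draws,
budget-bounded), and **adaptive** — a compact tree-structured-Parzen-style
sampler (no Bayesian-optimisation library exists in the target environment):
after a short random startup, trials are split at the 25% quantile into
good/bad sets, candidates are drawn from a kernel model of the good set, and
the good/bad density ratio selects the next trial. All strategies are
deterministic under a seed; ties in the argmax go to the earliest trial.

## The synthetic generator: what it emulates, what it does not

The generator emulates the *structure* the method assumes: 22 balanced
classes × 100 samples (2200 rows), seven features, class-conditional
distributions whose temperature/pH centres coincide with the knowledge base.
Per class, temperature ~ Normal(μ_T, fidelity·σ_T); pH the same truncated to
[0, 14]; the five non-physics features are truncated normals whose class
centres are drawn once per dataset and spread proportionally to `separation`
(default 3, a cleanly separable regime) with within-class spread proportional
to `noise_scale` (default 1, roughly 5% of each feature's plausible range).
Feature ranges (e.g. N in 0–140 kg/ha, rainfall 20–300 mm) are ordinary for
this schema. One integer seed drives everything, with per-class sub-streams
derived deterministically so class draws do not depend on class ordering;
truncated normals use the inverse-CDF construction (base R only), so
identical seeds reproduce identical values.

It does **not** emulate the real benchmark's feature covariances or
difficulty, and no attempt is made to match published accuracies on the
external dataset — those require the actual download and are excluded as
targets. A green label-recovery test therefore establishes that the pipeline
learns what it is pointed at, not field-level performance. `corrupt_dataset`
flips an exact fraction of labels and perturbs the non-physics features
(never temperature/pH, preserving the physics signal) for robustness
experiments.

## Numerical and degenerate-input choices

* Constant features MinMax-transform to 0 (avoids 0/0).
* Held-out values outside the training range map outside [0, 1] by design —
  the no-leakage property is asserted, not patched away.
* Classes with a single sample go to the training side of a split with a
  warning; classes with fewer than k members degrade folds to
  as-even-as-possible with a warning.
* Softmax and the boosting objective use max-subtraction for stability;
  boosting hessians are floored at 1e−12.
* Model files are a versioned RDS container (format name, format version,
  package version, class order, kb hash). JSON weights were rejected because
  tree ensembles make them impractically large.

## Time-budget scaling in the acceptance suite

The acceptance criteria that train the full four-base stacking model run
with explicitly reduced budgets (50/60 trees, 25 boosting rounds, 40 network
epochs) instead of the tuned defaults (116/441 trees, 465 rounds, 200
epochs), purely to fit a 1-CPU time budget. Generator settings — the stated
world — are never reduced. The physics-benefit criterion uses 10 fixed seeds
and asserts the *paired mean* improvement of λ = 0.1 over λ = 0 is
non-negative; the suite computes the actual margin at run time rather than
asserting any particular magnitude.

## Known limitations

* The shipped knowledge base is illustrative; conclusions about real crops
  require a validated table.
* Only temperature and pH constraints are implemented.
* The adaptive search is a compact TPE-style sampler, adequate for the small
  spaces used here but not a substitute for a mature optimisation library.
* The PINN trains on CPU in pure R matrix code: fine at benchmark scale
  (thousands of rows), not intended for large datasets.
* With balanced synthetic data the macro/weighted averaging distinction is
  nearly invisible; on imbalanced real data the choice matters and both are
  provided.
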