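---
title: "Dynamic prospect theory for sequential risky choice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic prospect theory for sequential risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpt)
```

## The scientific problem

In repeated risky monetary choice, people's decisions are not a fixed
function of the options in front of them: what happened on recent trials
shifts how the current gamble is valued and whether it is taken. `dynpt`
implements a complete analysis pipeline for quantifying these sequential
effects in a two-option gambling task, where each trial offers a 50/50
gamble (a possible gain and a possible loss, or a gain versus $0) against a
guaranteed amount, and the chosen option's outcome is realized immediately.

Three complementary analyses are provided:

1. a battery of nine random-intercept logistic regressions of the binary
   choice on the current options and lagged events (previous outcomes,
   previous decisions, previous expected values, valence, outcome type,
   lag depth, and outcome-by-option interactions), with log-likelihood
   ranking, likelihood-ratio tests for nested pairs and Wald tests for
   coefficient equality;
2. a dynamic prospect-theory model (PT+) in which the four valuation and
   choice parameters are updated trial by trial in proportion to the
   previous outcome; and
3. hierarchical Bayesian estimation of all eight PT+ parameters (four
   baselines, four updating terms) jointly across participants by MCMC,
   with split-chain Rhat and effective-sample-size diagnostics and a
   95%-credible-interval decision rule for whether updating terms are
   reliably nonzero.

A synthetic-task module simulates the whole design, so every stage of the
pipeline is testable end to end without access to any participant data.

## The PT+ model

Offered amounts are mapped to subjective utilities with a power value
function. A prospect paying $x \ge 0$ with probability $p$ is worth
$p\,x^{\rho}$; a prospect paying $x \le 0$ is worth
$-p\,\lambda\,(-x)^{\rho}$. The exponent $\rho > 0$ captures diminishing
sensitivity ($\rho < 1$ is risk averse for gains and, by reflection, risk
seeking for losses); $\lambda > 0$ multiplies losses ($\lambda > 1$ is loss
aversion). Probability weighting is the identity. The gamble's utility sums
its two equiprobable branches at $p = 0.5$; the guaranteed amount enters at
$p = 1$ (through the gain branch when non-negative, the loss branch
otherwise — the task never offers negative guaranteed amounts, but the model
is total).

Choice follows a softmax with inverse temperature $\mu \ge 0$ and a
value-independent decision bias $db$:

$$P(\text{accept}) = \left(1 + e^{-\mu\,(u(\text{gamble}) -
u(\text{guaranteed}) - db)}\right)^{-1}.$$

$\mu = 0$ is fully random choice; $db < 0$ biases toward gambling whatever
the amounts.

### Trial-by-trial updating

Each of the four parameters $\theta \in \{\rho, \lambda, \mu, db\}$ starts
at its baseline and is shifted after every trial by an updating term
$\delta^{\theta}$ multiplied by the previous trial's realized outcome,
rescaled linearly to $[0, 1]$:

$$\theta_1 = \theta_{\text{init}}, \qquad
\theta_t = \theta_{t-1} + \text{outcome}^{\text{scaled}}_{t-1}\,
\delta^{\theta}.$$

The scaling bounds are the dataset's full offered-outcome range (smallest
offered loss to largest offered gain), computed once per dataset. Because
the dynamics are additive, a trajectory depends on history only through the
cumulative scaled outcome — this is both a testable invariant and the root
of an identifiability ridge discussed below.

**Support floors.** Updating can drive $\rho$, $\lambda$ or $\mu$ toward
zero. A step that would cross below $10^{-6}$ is clamped there, and only
*downward crossings* are clamped: a parameter legitimately sitting at zero
(e.g. $\mu = 0$, the random-choice boundary) with no updating stays exactly
where it is. Floor applications are reported (`floored` flag in
trajectories). $db$ is unbounded.

## The synthetic task

`generate_trials()` emulates the design: gain-loss trials draw a gain
uniformly on $2–$12 and a loss equal to minus 0.25–2 times the gain,
against a $0 guaranteed amount (the guaranteed amount on these trials is
configurable; $0 matches the worked example and keeps the gamble-vs-nothing
structure); gain-only trials draw a gain on $2–$30 versus $0, against a
guaranteed $1–$12 strictly below the gain. Amounts are rounded to a $0.25
grid (the loss is clamped so its multiple of the gain stays inside
0.25–2 after rounding); the grid step is configurable, since the source
task specifies ranges rather than grids. Types are intermixed in random
order; the gain-loss fraction defaults to 2/3, reflecting that most trials
in this family of tasks are of the gain-loss type, and is a config knob
along with the per-participant trial count (140–180 is typical; the desk
default is 150).

`sample_individuals()` draws each participant's eight parameters from
independent normals on the *unconstrained* scale — $\log\rho$,
$\log\lambda$, $\log\mu$, raw $db$ and raw updating terms — so every draw
respects the supports. Default generating means are the published
group-level estimates ($\rho = 0.65$, $\lambda = 1.57$, $\mu = 22.2$,
$db = -0.58$, $\delta^{\rho} = 0.005$, $\delta^{\lambda} = 0.013$,
$\delta^{\mu} = 0.08$, $\delta^{db} = 0.03$). The population SDs are not
published; the defaults (0.2 on the log scale for $\rho$ and $\lambda$,
0.3 for $\mu$, 0.2 for $db$, and 0.01/0.01/0.05/0.02 for the four updating
terms) were chosen once to give the between-person heterogeneity typical of
gambling-task fits — roughly ±20–35% parameter spread and updating-term
variation comparable to the group means — and are not revisited.

What the generator does *not* emulate: reaction times and display timing,
payment bookkeeping, block boundaries (trials are one continuous sequence
per participant, so lagged regressors span the whole session), attention
lapses, and any drift not driven by outcomes. Passing recovery tests on
synthetic cohorts therefore demonstrates that the estimation machinery is
correct and calibrated for the assumed generative process, not that real
behavior follows PT+ dynamics.

```{r sim}
sim <- simulate_cohort(4, 20, seed = 1)
head(sim$trials, 4)
```

## The regression battery

All nine models share the response (choice of the gamble = 1) and the fixed
effects for the current risky gain, risky loss and guaranteed amount, plus
a per-participant random intercept. The models differ in their lagged
regressors; see `?build_design` for the full list. Coding decisions worth
stating:

* Previous decisions are coded +1 (gamble) / −1 (guaranteed) everywhere.
  With a 1/0 coding the slope would be exactly double and the intercept
  shifted; the sign and significance are unaffected.
* Lagged regressors are in dollars. Model 9's interactions are therefore
  also dollar-scaled; a `scaling` function is exposed in
  `loss_weight_illustration()` for rescaled variants.
* A $0 outcome from a lost gain-only gamble counts as a risky-gain-type
  outcome of amount 0 for the type-split models and has valence 0 for the
  valence model.
* Rows lacking the required lags are dropped per participant and the count
  reported (`n_excluded`).

Fits maximize the marginal likelihood by adaptive Gauss–Hermite quadrature
(15 nodes by default) via `lme4::glmer()`; random slopes are deliberately
not estimated, for reliable convergence at desk scale. Single-coefficient
p-values use the normal approximation; nested pairs are compared with the
likelihood-ratio test (`lrt()`), and coefficient equality within a model
with the Wald test (`wald_equality()`). Models with equal parameter counts
are ranked directly by log-likelihood (`compare_loglik()`).

The effect-size translation `indifference_probability()` asks: if the
current options contribute zero net logit, what gambling probability does a
previous-outcome slope imply? With the published slope of −0.03 per dollar,
a +$20 previous outcome gives 35% and a −$20 outcome 65%:

```{r fig2a}
fig_indifference_table(-0.03)[c(1, 21, 41), ]
```

## Hierarchical Bayesian estimation

The joint model places each participant's unconstrained 8-vector around
group-level means and SDs (normal on the unconstrained scale, so bounded
parameters remain in support for any draw), with priors: group means
normal — $\log\rho \sim N(\log 0.8, 1)$, $\log\lambda \sim N(\log 1.5, 1)$,
$\log\mu \sim N(\log 10, 2)$, $db$ and the updating terms $N(0, 1)$ — and
group SDs half-Cauchy with scale 1. These are broad, weakly informative
choices centered at canonical values from the risky-choice literature; all
are overridable through `pt_priors()`.

### The sampler

`run_mcmc()` runs a composite MCMC kernel written for this posterior's
geometry:

* **No-U-Turn updates (compiled)** on the joint non-centered state — group
  means, log group SDs and whitened individual offsets — with a diagonal
  mass matrix adapted during burn-in and the step size jittered per
  transition. The non-centered form removes the hierarchical funnel; the
  likelihood gradient is computed analytically in C++ by forward-mode
  accumulation through the sequential updating (support-floor crossings
  zero the affected partials).
* **Centered conjugate interweaves** after every trajectory: exact Gibbs
  draws of the group means, and parameter-expanded Gibbs draws of the
  half-Cauchy group SDs. Alternating centered and non-centered updates
  covers both the strongly and the weakly informed regimes.
* **Ridge moves.** The additive dynamics make a baseline and its updating
  term trade off almost perfectly (the data constrain roughly
  $\theta_0 + \bar{c}\,\delta^{\theta}$, with $\bar{c}$ the mean cumulative
  scaled outcome). Dedicated moves walk these ridges: a *delta-trade* move
  shifts every individual's updating term and compensates its baseline on
  the natural scale, and adapted 2-D and 8-D translation moves shift group
  means together with all individuals along covariances learned from the
  burn-in draws.
* **Prior-independence, translation and rescale moves** per coordinate,
  which mix the directions the data barely constrain and let the group SDs
  escape funnel necks.

A replacement per-participant log-likelihood can be supplied (used by the
test suite to check the sampler against a conjugate normal hierarchy with
a closed-form posterior); such likelihoods use a gradient-free fallback
kernel of adaptive single-site random walks plus the same interweaves.

Chains initialize at per-participant penalized likelihood modes with the
updating terms ridged toward zero (the neutral no-updating reference — an
updating term of 0.1 already shifts a parameter by several units over a
session), jittered per chain; a participant's initial offset is halved
until it sits within 100 log-units of its mode, because a large step in an
updating term compounds over the trial sequence.

### Diagnostics and decision rule

`rhat()` is the split-chain potential scale reduction; `effective_samples()`
is the chain-averaged autocovariance estimator with Geyer's
initial-positive-sequence truncation (capped at the total draw count).
A reported fit counts as converged when all group-level means have
Rhat < 1.01 and ESS > 400 (`glance()`); desk-scale defaults are 4 chains
of 1,500 draws with a 500-draw burn-in (a 20-chain, 10,000-draw preset is a
configuration, not a test requirement). An updating term is declared
reliably nonzero when its central 95% posterior interval excludes zero
(`ci95()`).

### Regressions on PT+-simulated cohorts

One caution on combining the two analysis families: on data simulated from
the dynamic PT+ model at the published group means, the model 1 regression
does *not* reliably recover a negative previous-outcome coefficient, even
though the underlying causal effect is present with the right sign and a
comparable magnitude (forcing a +$20 instead of a −$20 outcome at one
trial lowers the next trial's gamble logit by about 0.02 per dollar under
the group-mean dynamics — an assertion the test suite checks by direct
intervention). The reason is confounding, not error: with consistency
around 22 the latent choice state is strongly persistent, large realized
outcomes only occur after choosing the gamble, and the persistence channel
(a large positive previous-decision effect) cancels the causal updating
channel in the lagged-outcome coefficient. Real participants' behavior is
not literally PT+ at the posterior mean, so descriptive regression results
from real data should not be expected to reproduce on model-simulated
cohorts — a useful illustration of why the two analyses are complementary
rather than interchangeable.

### Known identifiability limits

Because scaled outcomes are bounded in $[0,1]$ and mostly positive, the
cumulative drift is nearly linear in trial number, so $(\mu_0,
\delta^{\mu})$ — and to a lesser degree the other baseline/updating
pairs — form long, flat posterior ridges at desk scale: a smaller baseline
consistency with strong positive updating fits almost exactly as well as a
large constant one. Once choices are near-deterministic the likelihood is
also flat *upward* in $\mu$. Marginal intervals for the $\mu$ pair are
therefore wide and can exclude a generating value even when the joint
posterior assigns it high density; the recovery criterion (coverage of at
least 6 of the 8 group means) reflects this. With many participants, longer
sessions, or trial sequences designed to decorrelate cumulative outcome
from trial number, the ridge tightens.

## Numerical choices

* Log-likelihoods use a numerically stable log-logistic; probabilities are
  clipped $10^{-12}$ from the boundary inside logs only (the sampler's
  internal evaluations are unclipped so that values and gradients match
  exactly).
* The likelihood-ratio statistic is clamped at zero after a tolerance
  check; a full model fitting materially worse than its nested model
  raises an estimation-quality error rather than a negative statistic.
* Ties in log-likelihood ranking are broken by input order (stable).
* Degenerate (constant) chains report `NA` ESS with a warning rather than
  a spurious count.
* All randomness flows through explicit integer seeds; a pipeline config
  (`pipeline_config()`) fully determines a run, and `run_pipeline()` writes
  a manifest with the config hash, seed, package version and per-stage
  status.

## Problem sizes used by the test suite

Unit tests run on cohorts of 2–8 participants and 15–60 trials. The
recovery experiments use: 50 participants × 150 trials for the
sign-recovery regression; 40 × 100 for the zero-variance pooled-logistic
oracle; 200 replicates of 10 × 50 for the Wald size check; and
20 participants × 150 trials with 4 chains × 1,500 draws for hierarchical
recovery. These sizes were chosen as the smallest designs at which the
checks are statistically meaningful.
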