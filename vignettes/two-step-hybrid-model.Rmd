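---
title: "Hybrid model-based/model-free analysis of the two-step Markov task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid model-based/model-free analysis of the two-step Markov task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepRL)
```

# The task and the scientific question

The two-step Markov task separates two modes of reinforcement learning.
On each of 200 trials a participant first chooses between two options;
each option leads with fixed probability 0.7 to its "common" second-stage
state (option 0 to state A, option 1 to state B) and with probability
0.3 to the other. In the second stage a further two-option choice is
rewarded with a probability that drifts from trial to trial as a
Gaussian random walk (step SD 0.025) reflected at 0.25 and 0.75, which
keeps participants exploring.

A *model-free* (MF) learner caches stage-1 action values from
trial-and-error and therefore repeats whatever was rewarded, regardless
of the transition that produced the reward. A *model-based* (MB)
learner plans through the known transition structure, so a reward
obtained after a *rare* transition makes it *switch* at stage 1.
The signature separating the two is the interaction between previous
reward and previous transition in the probability of repeating the
stage-1 choice ("stay probability").

The package implements the full analysis chain used in stress studies
of this task: task simulation, a seven-parameter hybrid MF/MB model
with MAP and hierarchical Bayesian fitting, behavioural quality
control, stay-probability contrasts, salivary-cortisol preprocessing,
and the group-level statistics, together with a calibrated synthetic
cohort generator so that every stage is testable without participant
data.

# The hybrid model

Latent values are a length-2 stage-1 MF vector $Q_{MF}$ and a
$2\times2$ stage-2 table $Q_2$ (state $\times$ option), all initialised
at 0 (rewards are 0/1, so every value stays in $[0,1]$). After a trial
with stage-1 choice $c_1$, stage-2 state $s$, choice $c_2$ and reward
$r$, in this order:

$$\delta_1 = Q_2(s, c_2) - Q_{MF}(c_1), \qquad
  Q_{MF}(c_1) \mathrel{+}= \alpha_1 \delta_1$$
$$\delta_2 = r - Q_2(s, c_2), \qquad
  Q_2(s, c_2) \mathrel{+}= \alpha_2 \delta_2, \qquad
  Q_{MF}(c_1) \mathrel{+}= \alpha_1 \lambda \delta_2$$

The MB values plan over the (instructed, fixed) transition matrix:

$$Q_{MB}(a) = 0.7 \max_b Q_2(\mathrm{freq}(a), b)
            + 0.3 \max_b Q_2(\mathrm{rare}(a), b)$$

Stage-1 choice follows a softmax over
$\beta_1\,[\omega Q_{MB} + (1-\omega) Q_{MF}] + \pi\,\mathbf{1}[a =
\text{previous } c_1]$, stage-2 over $\beta_2 Q_2(s,\cdot)$. The seven
free parameters are the learning rates $\alpha_1, \alpha_2 \in [0,1]$,
inverse temperatures $\beta_1, \beta_2 \ge 0$, eligibility trace
$\lambda \in [0,1]$, MB weight $\omega \in [0,1]$ — the quantity of
scientific interest — and the perseveration bonus $\pi$ (unbounded,
stage-1 only, keyed to the previous trial's stage-1 choice regardless
of reward).

Decisions taken where the model description leaves room:

* transition probabilities are known to the agent, never learned;
* missed trials update no values and clear the perseveration memory
  (no choice is fabricated);
* no forgetting/decay term — the parameter count excludes it;
* Q-values start at 0 (configurable through `task_config(q_init=)`).

# Fitting

`session_loglik()` sums the log-probabilities of both observed choices
over non-missed trials while replaying the updates above (C++ inner
loop; an independent naive R replay oracle checks it to $10^{-10}$ in
the test suite).

**Transforms and MAP.** Parameters are estimated on transformed scales:
logit for $\alpha_1, \alpha_2, \lambda, \omega$, log for $\beta_1,
\beta_2$, identity for $\pi$. `fit_map()` maximises the log-likelihood
plus independent Normal(0, 1.5) log-priors (Normal(0, 2) for $\pi$) on
those scales — weakly informative, mainly preventing divergence when a
parameter is unidentified (e.g. $\omega$ under $\beta_1 = 0$, which
reverts to the prior centre 0.5). Optimisation is BFGS from
`map_restarts` Latin-hypercube starting points; everything is
deterministic given the fit seed.

**Hierarchical model.** Subject-level transformed parameters are
$\theta_s \sim N(\mu, \mathrm{diag}(\sigma^2))$ with hyperpriors
$\mu_p \sim N(0,1)$ and $\sigma_p \sim$ half-$N(0,1)$. No MCMC engine
is available in the target environment, so the sampler is written in R
on top of the vectorised C++ likelihood: componentwise random-walk
Metropolis for each subject parameter (all subjects updated in one
likelihood pass), conjugate Gibbs draws for $\mu$, log-scale
random-walk updates for $\sigma$, and an interleaved ancillary
rescaling move that jointly scales $\sigma_p$ and the subject
deviations — the non-centred step that prevents the usual funnel when
the likelihood is weakly informative. Proposal scales adapt towards
acceptance 0.44 during warm-up only. Split-$\hat R$ and an
initial-positive-sequence ESS are reported for every group-level
quantity and every subject's $\omega$; a fit exceeding the $\hat R$
threshold is returned flagged, never suppressed.

The study-scale default is 4 chains $\times$ 6000 iterations (3000
warm-up); the package's tests run the documented desk scale of 2
$\times$ 1000 (500 warm-up), at which the convergence flag is often
raised for the weakly identified hyperparameters — that is expected
behaviour of the flag, and the $\omega$ recovery criterion is met
regardless. Shrinkage is validated on a cohort of subjects sharing one
true parameter vector, where pooling must (and does) reduce the spread
of the $\omega$ estimates relative to independent MAP fits; comparing
spreads on a *heterogeneous* cohort would confound shrinkage with the
true between-subject variance and is not a valid check.

# Behavioural quality control

A session is excluded when any of the following fires:

1. more than 20 missed responses (21 excludes, 20 does not);
2. either stage-1 option chosen on $\ge 95\%$ of non-missed trials
   (inclusive at the boundary);
3. previously rewarded stage-2 responses repeated at a rate strictly
   below 50%. Eligibility: pairs (t, next non-missed trial t') where t
   was rewarded and t' visits the same stage-2 state — the only pairs
   on which "repeating the rewarded second-step response" is defined.
   A session with no eligible pair leaves the rate `NA` and the rule
   unfired.

The 95% boundary being inclusive and the repeat-rate eligibility set
are interpretation choices; both are isolated in `qc_session()` and
pinned by tests.

# Stay-probability contrasts

`stay_table()` bins consecutive non-missed trial pairs by the previous
trial's reward and transition; pairs spanning a missed trial are
dropped, not bridged. `stay_contrasts()` pools cell counts across
subjects and fits a binomial logistic regression with $\pm 1/2$ effects
coding, so the third coefficient is the crossover (MB) interaction;
complete separation is detected and flagged.

One genuine limitation surfaced by simulation: finite 200-trial
sessions of a *pure MF* agent carry a small positive reward
$\times$ transition interaction (about +0.05 to +0.09 log-odds in
200-subject cohorts), strongest for $\lambda < 1$ but nonzero even at
$\lambda = 1$ — the drifting reward probabilities couple rewards to
transition history. This artifact is documented in the two-step
literature on TD agents. Consequently a cohort-level test that the
$\omega = 0$ interaction CI contains zero is sensitive to the
simulation seed, and a green result establishes the absence of a
*large* crossover, not of the artifact. The $\omega$-to-interaction
mapping remains strictly monotone, which the suite verifies across
$\omega \in \{0, 0.25, 0.5, 0.75, 1\}$.

# Cortisol and subjective ratings

Four salivary samples are taken: arrival (C1), after task instructions
(C2), 10 min after the stress/control procedure (C3), after the task
(C4). The analysis variables are `pre = ln(mean(C1, C2))`,
`post = ln(mean(C3, C4))` and the increase `d_cort = post - pre`.
Averaging precedes the log transform (a test guards against silent
reordering); the natural log is used — the base only rescales and is
absorbed by standardization; `d_cort` is computed on the log scale,
making it a unit-free log-ratio. A missing single sample is tolerated;
a fully missing pair marks the subject unusable for cortisol-dependent
analyses only. VAS ratings (0–10) enter as post minus pre differences.

# Group-level statistics

* Welch t-tests from raw data or from printed summary statistics
  (identical by construction), Mann–Whitney U (U reported for the
  first sample; exact p when small and tie-free, tie-corrected normal
  approximation otherwise), and Pearson chi-square on 2$\times$2 tables
  with Yates continuity correction by default.
* MAD outlier rule: points beyond $3 \times 1.4826 \times$ raw MAD
  from the median are removed, applied variable-wise to $\omega$ and
  `d_cort` with union removal before the regression. The 1.4826
  consistency constant follows the robust-statistics convention; both
  the constant and $k = 3$ are configurable.
* Normality screen: bias-corrected skewness and excess kurtosis
  divided by their small-sample SEs; "normal" means both scores inside
  the closed interval $[-3.29, 3.29]$.
* The headline test regresses standardized $\omega$ on group (HC = 0,
  AUD = 1, so a negative coefficient means lower MB weight in AUD),
  standardized `d_cort`, and their product; because HC is the
  reference, the `d_cort` main effect is the within-HC slope. An
  optional extra covariate (e.g. a working-memory score) enters
  standardized with its own `d_cort` interaction. Trimming the
  response tails inflates the null rejection rate slightly (~0.055 at
  n = 60, ~0.052 at n = 117 in 2000+ replicate simulations), a bias
  accepted as part of the published procedure.
* Bayesian Pearson correlation: the Bayes factor integrates the exact
  reduced likelihood of $\rho$ given $(r, n)$ against the default
  two-sided stretched-beta prior of width 1 (uniform on $[-1,1]$).
  Bayes factors are prior-dependent: software using a different
  default prior will print different values for the same $r$ and $n$.
* Power analysis by direct noncentral-t evaluation; d = 0.5 at 80%
  power and two-sided $\alpha$ = 0.05 gives 64 per group.
* The procedure (stress vs control) $\times$ time effect on cortisol
  or ratings is tested as a pooled-variance t on change scores,
  reported as $F = t^2$ with $(1, n-2)$ df — algebraically the
  interaction F of the 2$\times$2 mixed ANOVA (verified against an
  explicit `aov` oracle); the full multivariate repeated-measures
  analysis is out of scope.
* All p-values are two-sided; no multiple-testing correction is
  applied anywhere, matching the analysis being emulated.

# The synthetic cohort

`cohort_spec()` states the world the analysis assumes: 62 controls and
55 AUD subjects; a deliberately imbalanced stressor assignment (33/29
in HC, 40/15 in AUD across SECPT/warm-water control); lognormal
baseline cortisol (median 6.5 nmol/l, log-SD 0.5) with a log-scale
increase drawn from $N(0.35, 0.30)$ truncated at 0 under the stressor
and $N(0, 0.10)$ under the control, plus per-sample log-noise of SD
0.12; agent parameters drawn on their transformed scales around
typical two-step population values ($\alpha_1 \approx 0.5$, $\beta_1
\approx 4.5$, $\alpha_2 \approx 0.4$, $\beta_2 \approx 3.5$, $\lambda
\approx 0.6$, $\pi \approx 0.2$) independently of group; and
$\mathrm{logit}(\omega) = b_0 + b_g\,\mathrm{AUD} + b_d\,d +
b_i\,\mathrm{AUD}\,d + \varepsilon$, with $d$ the true log increase
and $\varepsilon \sim N(0, 0.80)$.

**Calibration.** The $\omega$-model coefficients are fixed so that the
*analysis-level* standardized regression — run on $\omega$ estimates
produced by the pipeline's own MAP fits, which attenuate effects by
roughly half relative to the latent $\omega$ — lands near the target
magnitudes (group $-0.5$, `d_cort` $-0.4$, interaction $+0.45$,
$R^2 \approx 0.15$) at the study's n. The frozen values are
$b_0 = 0.50$, $b_g = -1.27$, $b_d = -2.35$, $b_i = +2.55$; over probe
replicates the pipeline recovers mean standardized coefficients
$(-0.53, -0.42, +0.45)$ with $R^2 = 0.19$. Calibrating at the latent
level instead ($b_g = -0.61$, $b_d = -1.12$, $b_i = +1.18$, SD 0.64
reproduces the same targets from *true* $\omega$) is possible but
makes the end-to-end sign-recovery property unreachable under MAP
fitting — an instructive demonstration of two-stage attenuation. The
calibration was performed once, before the acceptance suite was run,
and is not revisited.

What the generator does *not* emulate: questionnaire psychometrics,
response times, practice/instruction phases, assay chemistry, and any
dependence of the non-$\omega$ parameters on group. A green end-to-end
test therefore establishes that the pipeline recovers the planted
$\omega$ structure from its own stated world, not that the world is a
complete account of real participants.

# Numerical choices

* Walk boundaries by reflection ($x' = 2b - x$), not clipping —
  preserves the marginal step SD; repeated folding handles extreme
  steps.
* One independent uniform substream per stochastic component
  (transitions, rewards, stage-1/stage-2 choices), each seeded via a
  stable string-hash rule (`derive_seed()`), so any component can be
  regenerated alone and C++ and R simulation paths are bit-identical.
* Softmax computed with max-subtraction; likelihood always finite for
  finite utilities.
* `integrate()` with rel.tol 1e-10 for the Bayes factor; the
  hypergeometric series is summed to machine tolerance. A sample
  correlation at $\pm 1$ returns an infinite Bayes factor.
* Mann–Whitney exact p only when both groups are $\le 50$ and
  tie-free.

# Known limitations

* The hierarchical sampler is random-walk based; at desk-scale
  settings the weakly identified hyperparameters ($\lambda$, the
  learning-rate SDs) mix slowly and the convergence flag fires. At the
  study-scale default settings mixing is adequate, but a
  gradient-based sampler would be preferable if one were available.
* The pooled stay-contrast regression treats trials as exchangeable
  across subjects; per-subject cell probabilities are available as a
  secondary output but no mixed-effects variant is provided.
* Whether the hierarchical fit should pool all subjects jointly or per
  group is left to the caller (fit the groups' session lists jointly
  or separately); the package default is joint, which mildly shrinks
  group differences and is therefore conservative for the group
  contrast.
* Exclusion of cortisol-sample corruption and similar data-availability
  facts are not computable rules and are out of scope.
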