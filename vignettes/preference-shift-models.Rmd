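---
title: "Random-preference discounting and Bayesian preference shift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-preference discounting and Bayesian preference shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasteshift)
```

This vignette is the package's account of its science: the choice models,
the social-inference model, the task simulator, the estimation machinery,
and the judgement calls made where the design was genuinely open.

## 1. Choice models

An option pair offers `R0` now against `RD > R0` after `D > 0` days. Under
hyperbolic discounting the delayed value is `V_D = RD/(1 + K*D)`, with
`K = e^k` the discount rate; larger `K` means more impulsive. The log
indifference point of a pair is `theta = ln[(RD/R0 - 1)/D]`: an agent with
`k < theta` prefers to wait.

Two accounts of choice variability are implemented:

* **KT** (`kt_policy`): softmax over values,
  `pi_D = 1/(1 + exp((Q0 - QD)/T))`. The temperature `T` is in the units of
  the rewards, and the noise is independent of the taste — a trembling
  hand.
* **KU** (`ku_policy`): a random-preference reading. The agent holds a
  Gaussian belief `k ~ N(m, u)`, samples one `k` per trial, and chooses
  deterministically, giving `pi_D = Phi((theta - m)/sqrt(u))`. Variability
  here *is* uncertainty, so observing a relevant other can rationally move
  the belief.

A note on `u`: it is treated as a **variance** throughout (the probit width
is `sqrt(u)`). The alternative reading (SD) appears in places in the
literature; the variance convention is fixed here because the
preference-shift algebra identifies the self-belief variance with `u`
directly, and a single convention across modules prevents silent
square/square-root errors. At `u = 0` the policy degenerates to a step
function with `pi_D = 0.5` exactly at indifference.

Two observation-layer transforms complete the set: `relax_policy` raises a
probability to the power `1/tau_o` (normalised), flattening unincentivised
choices made on behalf of another person (`tau_o = 1` identity,
`tau_o -> Inf` maps everything to 0.5); `apply_lapse` mixes in a
taste-independent uniform response with probability `xi`. The lapse belongs
to the preference-shift observation model; the bare KU and KT models carry
no lapse.

Inside all likelihoods, probabilities are clipped to
`[1e-12, 1 - 1e-12]` so that deterministic policies never produce `-Inf`;
the constant is `tasteshift:::PI_CLIP`.

## 2. The preference-shift (PS) model

The agent assumes that its own true taste `k_s` and the Other's `k_o` are
both drawn, with variance `sigma_r^2`, from a latent reference mean `k_r`
that is integrated out under a flat prior. Its information about itself is
the Gaussian likelihood `N(m_s, u_s)`; its information about the Other is
the Gaussianised likelihood `N(k_o_hat, var_o)` of the Other's observed
choices. Integrating out `k_r` and `k_o` gives the posterior self-belief as
a product of Gaussians,

    posterior var  = (1/u_s + 1/(2*sigma_r^2 + var_o))^-1
    posterior mean = weighted mean of m_s and k_o_hat with those precisions,

and symmetrically for the belief about the Other (`posterior_other`), whose
no-data limit is the self-belief widened by `2*sigma_r^2`. Two properties
follow and are enforced by tests: the posterior mean never overtakes the
Other, and the shift grows with `u_s` and shrinks with `sigma_r` — the
model-level counterpart of the population-level partial correlations.

Beliefs are stored as (mean, precision) pairs (`gaussian_belief`), with the
flat belief at precision 0, so no infinite-variance arithmetic occurs.

**Gaussianising the Other's likelihood.** The Other's observed choices enter
the algebra as a Gaussian, but a product of Bernoulli softmax terms is not
Gaussian. `other_likelihood_filter` evaluates the product of softmax
(`T = 1`, the Other's true generative temperature in the task) likelihood
terms on a grid `k in [-12, 2]` with 601 nodes, normalises, and
moment-matches mean and variance. The grid bounds comfortably cover the
population (`k ~ N(-4.5, 2.3^2)`) plus the ±2.3 offset of the Other; 601
nodes put the resolution at 0.023 ln-units, far below any posterior width
of interest.

**Filtering.** Beliefs about the Other used at trial `t` are computed from
the Other's choices on trials 1..t-1 only; the Other's choice on an
other-trial is revealed by the veridical feedback (binary choices, so
correct/incorrect identifies it). The participant's own guesses are not
evidence about `k_o`. The self-likelihood `(m_s, u_s)` is a static fitted
parameter pair; only the other-belief is filtered. Phase-3 other trials
continue to update the filter. The Other's own small lapse rate is ignored
in the participant's inversion model. Because the filter depends only on
the data (not on the PS parameters), it is computed once per dataset and
reused across all likelihood evaluations — this is what makes whole-dataset
`ps_loglik` cheap enough for multi-start optimisation and MCMC.

Per-trial policies (`ps_trial_policy`): self trials use the posterior
self-belief, a KU read-out, then the lapse mix; other trials use the
posterior other-belief, a KU read-out, then the `tau_o` relaxation. During
phase 1 the other-belief is flat and the model reduces exactly to KU with
lapse.

## 3. The task simulator

`simulate_participant` runs the three-phase DID protocol:

* **Phase 1** (60 trials): 30 from a standard set whose indifference points
  are evenly spaced over `[-9, 0]` ln-units, interleaved with 30 selected
  adaptively. A grid posterior over the participant's `k` (softmax
  likelihood at `T = 1`) is tracked after every choice; each adaptive trial
  scores 200 random candidate pairs by expected posterior entropy over the
  two predicted choices and presents the minimiser (ties to the first
  candidate).
* **Phase 2**: the Other's `k_o` is set from the phase-1 posterior mode
  `k_b`, shifted by one population SD (2.3) towards the population mean
  (-4.5) with probability 2/3, away with 1/3. The participant guesses the
  Other's choice, the Other's actual choice is sampled from the softmax
  policy at `T = 1`, and veridical feedback follows. The phase stops at 8
  correct of the last 10 (a full window of 10 is required) or at 60 trials.
* **Phase 3**: interleaved mini-blocks of 10 choose-for-self and 10
  choose-for-other trials; 3 blocks per role by default (the study count is
  not published; the default is configurable).

**Option menus.** Reward magnitudes and delay menus are likewise not
published. Pairs are built to hit a target indifference point exactly:
`R0` cycles over 1..10 currency units, `D = round(c * exp(-k))` clamped to
`[1, 365]` days, `RD = R0*(1 + D*e^k)`, keeping reward ratios in a
plausible (1, 5] band. Phase-2/3 menus interleave random pairs with
entropy-adaptive ones exactly as phase 1 does ("options much like phase
1"), scored against the running posterior for whoever the trial is about —
the participant's own `k` on self trials, the Other's `k_o` on other
trials. This matters for inference quality: uniformly random menus leave
most trials far from the relevant indifference point, where choices are
deterministic and carry almost no information about the shift.

**Populations.** `simulate_population` draws agents from configurable
distributions; the defaults encode the study conditions where stated and a
field-plausible choice otherwise: `m ~ N(-4.5, 2.3^2)` (stated), `u`
log-normal with median 1 and ln-SD 1 (spanning near-deterministic to highly
variable choosers, matching the observed spread of fitted temperatures),
`sigma_r` log-normal with median 1.1 (near the reported mean fitted value,
about half the population dispersion), `tau_o` log-normal with median 1.5,
`xi ~ Beta(1, 60)` (median near the reported 0.015) for PS cohorts, ages
uniform 14–24. `m` and `u` are drawn independently — the condition under
which the spurious softmax `k`–`ln T` coupling is a parameterisation
artifact rather than a population fact. Everything is reproducible from a
single seed.

What the simulator does **not** emulate: inattention drifts and session
effects, menu idiosyncrasies of the deployed task, payment realisation,
individual departures from hyperbolic discounting, and any strategic
reasoning about the Other. Passing recovery tests therefore shows that the
estimation machinery is correct under the model's own assumptions, not that
real data satisfy them.

## 4. Estimation

Fitting operates on an unconstrained transformed scale — identity for
location parameters, log for `u`, `T`, `sigma_r`, `tau_o`, logit for `xi` —
inside a search box of ±12 transformed units.

* `map_fit`: multi-start L-BFGS-B on the log-posterior (flat
  transformed-scale priors when none are given), numerical Hessian at the
  mode for the Laplace covariance. Fits on one-sided degenerate data or at
  the search box are flagged `boundary` and not `converged`.
* `mcmc_fit`: component-wise adaptive random-walk Metropolis. This stands
  in for hit-and-run-style component-wise Metropolis samplers: on these
  low-dimensional, unimodal posteriors the two target the same distribution
  and the random-walk variant is simpler to verify. Proposal scales adapt
  towards 0.44 acceptance during warm-up, then freeze. Point estimates are
  posterior medians (medians commute with the monotone transforms).
  Convergence requires an effective sample size of at least 100 on every
  parameter (Geyer initial-positive-sequence estimator) and a Geweke-style
  early/late stationarity check (|z| <= 3). Defaults (20 000 post-warm-up
  iterations, thinning 10) are a desk-scale setting; million-sample budgets
  remain configurable.
* Weakly informative default priors (`default_priors`): normal(-4.5, 5) on
  locations, normal(0, 3) on log-scales, normal(-3.5, 2) on the logit
  lapse — wide enough to be dominated by 60 trials, tight enough to keep
  degenerate participants (who always wait or never wait) from running to
  the search box. Cohort-level KT/KU fitting uses these priors; the
  plain-MAP definition of `k_b, T_b` with flat priors remains the
  `map_fit` default for single datasets.
* `empirical_bayes_refit`: stage (i) drops non-converged stage-1 fits;
  stage (ii) fits a Gaussian per parameter on the transformed scale over
  the sample; stage (iii) refits **every** participant (including the
  dropped ones) under these sample priors. On simulated cohorts this
  shrinks estimates towards the sample mean and improves rank recovery of
  the weakly identified parameters (`sigma_r`, `tau_o`).
* `compare_models`: per-participant log-likelihood and BIC differences on
  identical trials (enforced), fraction favouring each model with ties
  counted half and a binomial SEM, Wilcoxon signed-rank test, total BIC
  difference, and the fractions beyond the conventional positive (2) and
  strong (6) BIC thresholds.
* `fit_perturbation_model`: KU with separate `m1`/`m3` and shared `u` over
  self trials — the mechanism-agnostic comparator that can absorb any
  shift. Its BIC opponent is the single-`m` comparator (`"ku_static"`)
  fitted to the same trials, so the tally isolates the evidence for *any*
  between-phase taste change against the extra-parameter penalty.

`BIC = -2*LL + p*ln(n_trials)` is stored on every fit and recomputable from
its parts.

## 5. Population statistics

`population_table` joins fits and ground truth one row per participant. The
signed shift is `(m3 - m1) * sign(k_o - m1)`: positive when the taste moved
towards the Other. The absolute shift `|m3 - m1|` is also exposed — age
analyses conventionally use the magnitude, the shift regression the signed
version; both columns are present so either convention can be applied
explicitly.

Partial correlations (`association_stats`) are computed by double OLS
residualisation, with degrees of freedom reduced by the number of controls.
"Mediation" (`mediation_by_partial`) is the partial-correlation notion:
full mediation of x–y by m is declared when raw r(x, y) is significant,
partial r(x, y; m) is not, and partial r(m, y; x) is. `shift_regression`
fits `shift ~ u * sigma_r` by OLS, interaction included. The near-zero-`u`
flag threshold is 0.01 (configurable) — agents below it behave
deterministically on every offered pair.

## 6. Numerical choices and degenerate inputs

* Probability clipping at `1e-12` in all Bernoulli likelihoods.
* `relax_policy` works in log space, so extreme probabilities and small
  `tau_o` do not overflow; 0 and 1 are exact fixed points.
* Flat beliefs are precision-0 states; a posterior from two flat components
  is an error (improper), not a NaN.
* Grid posteriors that vanish numerically (all-zero mass) raise an error
  rather than renormalising noise.
* Adaptive-selection ties break to the lowest candidate index,
  deterministically.
* Degenerate all-one-sided datasets are fittable but flagged (`boundary`),
  and are excluded from empirical-Bayes prior construction while still
  receiving stage-3 estimates.
* The transformed-scale search box (±12) bounds `exp` overflow; hitting it
  flags the fit.

## 7. Problem sizes

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the qualitative phenomena are statistically stable:
equation oracles on 100-point parameter sweeps and 10^6 Monte-Carlo draws;
recovery on 50 full-task PS participants; model recovery on 100 phase-1
cohorts per generating model; the softmax-artifact cohort at the study's
own sample size of 738 (phase 1 only). MCMC-based checks use short chains
on two-parameter models; the PS model's MCMC path is exercised but cohort
fitting defaults to MAP, which the sampler agrees with on well-identified
data.

## 8. Known limitations

* `sigma_r` and `tau_o` are weakly identified per participant; their
  per-individual estimates are noisy (rank correlations with truth around
  0.6–0.8 under empirical Bayes at 50 participants) and population-level
  statements should lean on the EB fits.
* The Gaussian moment-matching of the Other's likelihood is exact only
  asymptotically; with very few, one-sided observations the matched
  variance can exceed what a conjugate analysis would give.
* The perturbation-model tally on synthetic PS cohorts is large by
  construction (their tastes really do shift); the analogous tally on real
  data answers a different question — whether shifts escape the main
  model — and the two should not be compared numerically.
* The simulator's in-task estimate `k_b` assumes `T = 1`, as the deployed
  task did; it is deliberately "highly approximate", and the package keeps
  that property rather than improving it, since the Other's placement
  depends on it.
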