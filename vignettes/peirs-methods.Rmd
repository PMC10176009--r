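---
title: "Risk-sensitive reinforcement learning with PEIRS: models, simulation, and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-sensitive reinforcement learning with PEIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

People evaluate risk differently when outcome probabilities are described
explicitly than when they must be learned from repeated feedback (the
description-experience gap). In experience-based tasks, humans tend to be
risk-seeking among high-value options and risk-averse among low-value options;
with described gambles the pattern reverses. Metabolic state (hunger) has been
reported to modulate the learned — but not the described — pattern,
flattening contextual risk attitudes toward neutrality.

`peirs` packages the full computational workflow used to study this question
on synthetic cohorts: simulators for the two tasks, a risk-sensitive
reinforcement-learning model (PEIRS) and its Rescorla–Wagner (RW) baseline,
hierarchical empirical-Bayes fitting, Bayesian-Information-Criterion (BIC)
model comparison, parameter-recovery diagnostics, and the behavioral
statistics that express the contextual risk-preference contrasts.

## The two tasks

**Experience task.** Four stimuli carry approximately Gaussian reward
distributions crossing mean (35 or 65 points) with standard deviation (5 or
20). A session has four blocks of 72 trials: per block, 18 high-context trials
(the two mean-65 stimuli), 18 low-context trials (the two mean-35 stimuli),
24 mixed trials (one of each mean, an attention control), and 12 forced
single-option trials (3 per stimulus, guaranteeing exposure). A forced trial
on stimulus X never immediately precedes a high/low-context trial offering X
(`experience_schedule()` enforces this by constrained shuffling with local
swap repair, bounded at 10,000 attempts). Stimulus identities are replaced by
a fresh, statistically identical set after two blocks.

Rewards are drawn per block and affinely standardized so each block's
empirical mean and SD equal the stimulus specification exactly before
rounding (`pregenerate_block_rewards()`); values are rounded to integers and
clipped to the 0–100 display scale at consumption. The clipping point is at
least 1.75 SD away for the widest distribution, so clipping is rare; the
Monte-Carlo bias it induces on the mean is below half a point.

**Description task.** Ten unique two-option gambles, each played twice per
20-trial block across four blocks. Gambles 1–8 pit a 50:50 ±10 "safe" option
(expected value 0) against a risky option crossing win probability (0.6/0.4),
win magnitude (30/70), and loss magnitude (30/70); risky expected values span
−30 to +30. Gambles 9 and 10 are the low- and high-reward context probes:
expected-value-matched pairs that are sign-flip mirrors of each other. Their
exact point magnitudes are configurable (defaults: certain ±40 versus a
50:50 ±80-or-0 gamble); only the equal-EV and valence-mirror structure is
fixed by the design.

## The models

Both models learn the expected value of the chosen stimulus by the delta rule

$$Q_{c,t+1} = Q_{c,t} + \alpha_Q (r_t - Q_{c,t}),$$

and choose between two offered options by the softmax rule
$P_c = 1/(1 + e^{-\beta (U_c - U_u)})$. For RW the utility is simply
$U = Q$. PEIRS additionally tracks the *spread* of outcomes from unsigned
prediction errors,

$$S_{c,t+1} = S_{c,t} + \alpha_S (|r_t - Q_{c,t}| - S_{c,t}),$$

which converges to the mean absolute deviation of the reward distribution
($\sigma\sqrt{2/\pi}$ for a Gaussian), and values options as

$$U_{c,t} = Q_{c,t} + \gamma_0 S_{c,t} + \gamma_1\, \delta_{\text{context}}\, S_{c,t},$$

where $\delta_{\text{context}}$ is the mean estimated value of the offered
stimuli minus the mean estimated value of all four stimuli in the current
set. With estimates at the true means the signal is +15 points in high- and
−15 in low-reward contexts. $\gamma_0$ is a context-independent risk
propensity; $\gamma_1$ converts the context signal into context-dependent
risk weighting (positive values: risk-seeking in high-reward, risk-averse in
low-reward contexts). Setting $\gamma_0 = \gamma_1 = 0$ reduces PEIRS to RW
exactly — simulation and likelihood are then trial-for-trial identical, which
the test suite asserts.

Two numerical choices deserve note. First, the spread update uses the
*unsigned* deviation $|r - Q|$: S is a dispersion estimate and must stay
non-negative; a signed version would converge to zero and make the utility
degenerate. Second, the context signal is computed from the agent's current
value estimates, not the true means, so it starts near zero and grows as the
stimulus values are learned — an important dynamic for identifiability (see
below).

Initial estimates are $Q = 50$, $S = 5$ for every stimulus. Forced trials
update the chosen stimulus's Q and S but contribute no choice term to the
likelihood (their single option is taken with probability 1); `session_loglik()`
therefore sums log softmax probabilities over two-option trials only, while
the state update runs over all trials. The likelihood kernel is compiled
(Rcpp) because hierarchical fitting evaluates it millions of times; an
independent pure-R replay (`replay_session()`) exposes the full latent trace
and must agree with the compiled path to machine precision.

## Hierarchical fitting

Fitting is empirical-Bayes expectation–maximization on an unconstrained
scale: learning rates are logit-transformed, $\beta$ log-transformed, and the
$\gamma$s unchanged. Each E-step computes each subject's
maximum-a-posteriori (MAP) estimate under the current Gaussian population
prior by multistart BFGS (10 starts initially: the prior mean plus prior
draws; warm starts on later iterations), with posterior variances from the
Laplace approximation (diagonal of the inverse Hessian of the negative
penalized objective; if the Hessian cannot be inverted the prior variance is
used, i.e. "no information"). Each M-step moment-matches the prior:
$\mu \leftarrow \text{mean}(m_i)$,
$\sigma^2 \leftarrow \text{mean}(m_i^2 + v_i) - \mu^2$, floored at $10^{-6}$.
Iteration stops when no prior mean or variance moves by more than $10^{-3}$,
or after 100 iterations. Conditions are fitted separately.

The starting prior is deliberately scale-aware: wide on the transformed
learning rates (variance 2.25) and $\log\beta$ (variance 1), but matched to
the natural magnitude of the risk weights (variances 0.25 and 0.01), which
multiply a points-by-spread product where values of order 0.01–0.3 already
produce large behavioral effects.

Model comparison uses per-subject BIC,
$-2\,\text{loglik} + k \ln n_{\text{choice}}$, with the likelihood-only value
at the MAP, $k = 5$ (PEIRS) or $3$ (RW — the spread learning rate is retained
in the RW state space even though the spread never enters its utility, so the
two models share a state representation), and $n_{\text{choice}}$ the number
of two-option trials (240 of 288). Cohort summaries report per-subject
preferences and summed BICs. Condition contrasts on fitted parameters use
paired t-tests on the unconstrained MAPs with Bonferroni correction across
the five parameters.

## The synthetic-agent generator

The generator is the package's definition of the study conditions, and its
defaults are fixed rather than tunable per analysis. Locations were chosen to
reproduce the qualitative behavioral anchors of the task: $\beta$ centered at
0.135 yields mixed-trial accuracy above 90% once values are learned;
$\gamma_0$ is centered at 0 (no baseline risk propensity); learning rates
center at 0.30. Sample-based value learning is intrinsically risk-averse for
high-spread options (the "hot-stove" effect: a low-fluctuating Q estimate
stops being sampled and stays low), which puts the $\gamma = 0$ baseline
risky-choice rate near 0.43 rather than 0.5; the sated $\gamma_1$ location
(0.045) is calibrated against that measured baseline so the sated cohort
shows the mild high-context risk-seeking the task is known for,
p(risky | high) ≈ 0.6–0.65 after learning. The hungry regime lowers
only the spread learning rate (to a 0.12 center) and the context sensitivity
(to 0.005), the two parameters through which metabolic state is taken to act;
within-subject cohorts share each subject's standard-normal draw across
conditions so the hunger contrast is a pure location shift.

Population scales (0.7 on logit learning rates, 0.5 on $\log\beta$, 0.2 on
$\gamma_0$, 0.02 on $\gamma_1$) were set by a design-stage Fisher-information
argument: with 144 context trials per session, the per-subject standard error
of $\gamma_1$ is roughly 0.008 and of $\gamma_0$ roughly 0.12, so
between-subject scales of 0.02 and 0.2 make individual differences
resolvable within one 288-trial session while keeping simulated behavior in
the empirically observed range.

What the generator does *not* emulate: reaction times, attention lapses,
choice perseveration or other history effects beyond the model, subjective
rating noise, and session-order effects. Passing tests therefore demonstrate
internal consistency of the pipeline under the model's own assumptions, not
that real participants are PEIRS agents.

## Parameter recovery and its limits

`parameter_recovery()` samples agents from the dispersed default population,
simulates each on its own schedule, refits the cohort with the full
hierarchical EM, and correlates generating against recovered parameters on
the unconstrained scale. At the 32-agent scale, $\alpha_Q$, $\beta$,
$\gamma_0$, and $\gamma_1$ recover well (R roughly 0.90, 0.90, 0.81, 0.82 in
our runs).

The spread learning rate $\alpha_S$ is the structural exception, and the
package reports it honestly rather than adjusting the conditions until it
passes. $\alpha_S$ influences choice only through $\gamma_0 S$ and
$\gamma_1 \delta S$; early in a session, when the S trajectory still carries
information about its learning rate, the learned context signal $\delta$ is
still near zero, so most of the $\alpha_S$ signature cancels out of the
choice stream. A flat-prior per-subject maximum-likelihood fit — the
identifiability ceiling, with no shrinkage at all — already tops out near
R ≈ 0.71 under the default population, and the EM's marginal-likelihood
estimate of the $\alpha_S$ population variance is noise-dominated at
n = 32 (implied per-subject Fisher information ≈ 0.5), so it settles well
below the generating variance and the resulting over-shrinkage attenuates
the recovered $\alpha_S$ further (R ≈ 0.45–0.65 depending on the seed). The
same mechanism inflates the worst cross-parameter correlation (true
$\alpha_Q$ against recovered $\alpha_S$) to |R| ≈ 0.27–0.42. This is a
property of the model-task combination under a dispersed generating
population, not of the optimizer: fit-refit agreement is exact, and the
Laplace variances are self-consistent across prior widths. Recovery studies
that sample generating values from a *fitted* cohort prior (typically much
less dispersed in the weakly-identified directions) will report higher
$\alpha_S$ recovery and smaller cross-correlations.

## Behavioral statistics

Risk preferences on the experience task are computed from the second half of
each 144-trial stimulus set (after learning has stabilized): the proportion
of high/low-context choices selecting the high-spread stimulus, pooled across
sets, plus mixed-trial accuracy over all mixed trials. On the description
task all trials count (no learning): gamble 9 gives the low-context and
gamble 10 the high-context risky proportion, and gambles 1–8 give accuracy as
the fraction of higher-EV choices.

The 2×2 fully-within ANOVA (`rm_anova_2x2()`) is computed from first
principles via per-subject difference contrasts, for which each effect's F is
exactly the squared paired-t statistic with df = (1, n−1) and partial
$\eta^2 = F/(F + n - 1)$; the test suite verifies exact agreement with
`aov()`'s error-stratum decomposition. The signed-rank test drops zero
differences, midranks ties, and uses the tie-corrected normal approximation
with continuity correction; it is validated against exact enumeration of the
$2^{10}$ sign assignments on a 10-pair example. Model-derived stimulus
utilities (`stimulus_utility()`) use the single-stimulus context signal
$\delta = Q_{\text{stim}} - \overline{Q}_{\text{set}}$, appropriate when one
stimulus is evaluated in isolation, as on rating screens.

## Problem sizes and reproducibility

All simulation scales are package choices made once: cohorts of 32 subjects
with 288-trial sessions for recovery and model selection, 50 replicate
cohorts for the surrogate hunger-by-context power check, and small (4–8
subject, 1–2 block) configurations for unit-level checks. Every public
entry point takes a seed, and sub-seeds for schedules, reward streams, and
choice streams are derived hierarchically from the run seed, so adding
subjects does not perturb existing ones and any artifact regenerates
byte-identically from its persisted configuration (`run_pipeline()` writes
the configuration, all intermediate CSVs, and an md5 manifest).

```{r example}
library(peirs)

# one agent, one session
sched <- experience_schedule(seed = 1)
sim <- simulate_subject(peirs_params(0.3, 0.3, 0.15, 0, 0.03), sched, seed = 2)
risk_preference_experience(tidy(sim))

# a two-condition within-subject cohort and its interaction test
pops <- default_populations()
coh <- simulate_within_cohort(pops$sated, pops$hungry, n = 32, seed = 3)
prefs <- risk_preference_experience(coh$trials)
long <- tidyr::pivot_longer(prefs, c(p_risky_high, p_risky_low),
                            names_to = "context", names_prefix = "p_risky_",
                            values_to = "p_risky")
rm_anova_2x2(long, dv = "p_risky", within = c("condition", "context"))

# hierarchical fits and model comparison for one condition
sated <- dplyr::filter(coh$trials, condition == "sated")
fit_p <- fit_population_em(sated, model = "peirs")
fit_r <- fit_population_em(sated, model = "rw")
compare_models(fit_r, fit_p)
```

## Known limitations

- The RW baseline carries a prior-identified spread learning rate (k = 3) so
  that both models share a state space; its estimate is meaningful only
  through the prior.
- $\alpha_S$ recovery is information-limited under dispersed generating
  populations (see above).
- The description task is fitted by no model (only analyzed behaviorally);
  the pluggable policy family exists to generate fixtures, not to claim a
  process account.
- The EM uses a Laplace approximation and moment-matching; it is not a full
  Bayesian treatment, and population variances of weakly-identified
  parameters should be interpreted with caution.
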