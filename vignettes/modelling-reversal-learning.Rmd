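---
title: "Modelling serial-reversal Pavlovian conditioning with pavlovhmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serial-reversal Pavlovian conditioning with pavlovhmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavlovhmm)
```

## The task and what the generator emulates

The package models a two-session Pavlovian conditioning protocol. In each
120-trial session, pairs of cues are presented one at a time; one cue of the
current pair predicts a valenced liquid (pleasant in the appetitive session,
unpleasant in the aversive one) and the other a neutral liquid, each
delivered with probability 0.6 on presentation (otherwise nothing is
delivered). Every contingency phase lasts at least 16 trials, after which a
per-trial trigger with probability 0.25 ends it: within a pair the trigger
causes a reversal (the cues swap liquids), after a reversal it introduces a
fresh pair. Three pairs appear per session and each reverses exactly once.
The currently neutral cue appears exactly twice in every non-overlapping
four-trial window, sides are random, and inter-trial intervals are uniform
on 2–11 s.

`generate_session()` reproduces this schedule. One point required a design
decision: a literal reading of the trigger rule leaves the session length
open-ended, yet the protocol fixes 120 trials. We reconcile the two by
rejection sampling — the six geometric phase extensions are redrawn until
they total 120 trials — so that every seed yields a complete session with
all six phases. Because this conditioning slightly distorts the empirical
hazard (extensions are constrained to sum to 24), an unconstrained mode
(`fixed_length = FALSE`) is retained; the per-trial hazard estimated from it
(`empirical_trigger_hazard()`) is an unbiased check of the 0.25 design
value. The neutral-cue balance is enforced mechanically by shuffling two
neutral and two valenced slots within each aligned four-trial window; the
protocol states the constraint but not its mechanism, and any mechanism
satisfying the window counts is observationally equivalent at the level the
models see. Inter-trial intervals are generated for completeness but ignored
by all fitting — every model is trial-indexed.

```{r generator}
sess <- generate_session(task_config(), seed = 1)
sess
validate_session(sess)$violations
```

## The hidden Markov learner

The model-based learner maintains a joint belief over the contingency state
$S$ (which cue of the pair carries the valenced liquid; the concurrent
"both valenced" configuration is excluded from the state space) and a
binary reversal-expectation node $H$. The $H$ transition is absorbing,

$$P(H_t = 1 \mid H_{t-1} = 0) = \alpha, \qquad
  P(H_t = 0 \mid H_{t-1} = 1) = 0,$$

and the state transition is conditional on $H_t$: identity under $H_t = 0$,
a symmetric swap with probability $\beta$ under $H_t = 1$. Observations are
cue–outcome combinations with emission probabilities 0.6 (delivery of the
liquid the state assigns to the presented cue) and 0.4 (no delivery); the
outcome that the state assigns to the *other* cue has likelihood zero, which
is what makes single observations so informative in this task.

Conventions fixed in the implementation:

* **Reset.** At each new-pair onset the belief is reset to uniform over $S$
  with $H = 0$ exactly; the transition operators apply only from the second
  trial of a pair onward. Hence on the second trial the learner already has
  probability $\alpha$ of expecting a reversal.
* **Anticipatory readout.** The expected value
  $Q_j = \sum_S P(S)\,0.6\,R_{j|S}$ and the precision are recorded on the
  *predictive* belief at cue onset — after the transition step, before
  conditioning on the trial's outcome — because they model anticipatory
  responses to the cue. ($R$ is $+1/0/-1$ for pleasant / neutral /
  unpleasant liquids, so $|Q| \le 0.6$ always.)
* **Precision.** "Inverse entropy" is implemented as normalized negentropy
  $1 - H(P)/\log_2 K$, which is bounded in $[0, 1]$; a literal reciprocal
  $1/(H + 10^{-6})$ is available behind `precision_mode = "reciprocal"` but
  diverges at point-mass posteriors, which is why it is not the default.
  Both are strictly decreasing in entropy, so they order trials
  identically.
* **Numerics.** Belief updates run in linear probability space with explicit
  renormalization every trial; traces are 120 trials long, so underflow is
  not a concern. The tests verify the filter against a brute-force
  enumeration of all joint $(S, H)$ paths on short sessions (agreement to
  $10^{-10}$) and against an independent log-space recursion.

The reduced learner (`reduced_hmm_filter()`) clamps $H = 1$, giving a
constant swap hazard $\beta$. Its expected values track the full model's
almost perfectly, but its precision has no anticipatory decline: with the
full model, precision erodes between reversals as the reversal expectation
grows, even while every outcome confirms the current contingency.

```{r hmm}
tra <- hmm_filter(sess)
red <- reduced_hmm_filter(sess)
trace_correlation(tra$ev, red$ev)
```

## Choosing $\alpha$ and $\beta$

The transition parameters are fixed a priori, not fitted. $\beta = 0.25$ is
the task's own trigger hazard — the value an ideal observer told the
protocol would use. $\alpha$ has no such anchor; we calibrate it against the
one quantitative diagnostic available for this model class, the correlation
between the full and reduced learners' expected-value traces, which for this
task sits near 0.987 (appetitive) / 0.986 (aversive). The sweep below shows
the diagnostic is monotone in $\alpha$ at fixed $\beta$; $\alpha = 0.3$
places it in that band, and is the package default. Model fits themselves
are famously insensitive to these values, which is why
`hmm_sensitivity_sweep()` ships as a utility rather than a fitting step.

```{r sweep, eval = FALSE}
hmm_sensitivity_sweep(alphas = c(0.1, 0.2, 0.3, 0.5),
                      betas = c(0.15, 0.25), n_sessions = 19, seed = 1)
```

## Model-free comparators

The Rescorla–Wagner, Pearce–Hall and Hybrid rules update only the presented
cue's value, resetting at each new-pair onset, with reward coded 1 iff the
valenced liquid was delivered and 0 otherwise — *in both sessions*. This
salience coding in the aversive session is deliberately asymmetric to the
HMM's signed $-1$ coding: the model-free rules as used for this task track
outcome occurrence, not outcome sign. Two further conventions the
literature leaves open: Pearce–Hall associability is tracked *per cue* and
initialized at 1 for a fresh cue (maximal attention to novel stimuli), and
the Hybrid rule's searched parameter is the associability decay $\eta$ with
the learning-rate scale $\kappa$ fixed at 1. Note that the Pearce–Hall rule
as written (`Q ← Q + S·assoc·R`) is not a convex update and can transiently
push values above 1 at high intensity; the traces report such excursions
rather than clipping them.

The baseline model holds EV at 0.5; for regression it receives a small
seeded Gaussian jitter (sd 0.01 — "small" relative to the 0–1 EV range, two
orders below it) because a constant regressor is singular.

## Reaction-time fitting

`adjust_rts()` log-transforms RTs and removes an intercept, a linear trend
over trials, and a side-switch cost by least squares, dropping missing
responses listwise (a subject missing more than half of a session's
responses is excluded by `fit_sessions()`). Each model's EV trace is then
regressed against the adjusted residuals; free parameters are searched on a
grid over $[0, 1]$ (step 0.001 by default). One numerical choice matters:
the EV regressor is residualized against the same nuisance design before
the second regression (Frisch–Waugh), making the two-step fit identical to
the joint regression. Without this, the nuisance columns absorb part of the
EV signal and parameter recovery is biased by about 0.02 even at vanishing
noise; with it, recovery is exact to the grid step, which the tests
enforce.

Fits are scored by the Gaussian-residual BIC, $n \ln(\mathrm{SSE}/n) + k
\ln n$, counting only the learner's free parameters ($k = 1$ for RW, PH,
Hybrid; $k = 0$ for the fixed-parameter HMMs and the baseline), and
$-\mathrm{BIC}/2$ serves as the approximate log model evidence downstream.
Fitting is per subject × session, which yields the subject-level evidences
that random-effects selection needs; a pooled mode (one grid search over
all subjects' concatenated residuals, $n$ = total trials) is also provided,
matching the degrees-of-freedom description used for group-level tables.

## Model selection and baseline validation

`bms_random_effects()` implements the standard variational random-effects
scheme: a Dirichlet(1, …, 1) prior over population model frequencies,
subject responsibilities $\propto \exp(\text{log evidence} + \psi(\alpha_k)
- \psi(\sum \alpha))$, iterated to $10^{-8}$ on the counts. Posterior
probabilities are the normalized Dirichlet means; exceedance probabilities
are Monte-Carlo estimates ($10^6$ draws by default, seeded, standard error
$\lesssim 10^{-3}$) of each model being the most frequent. The tests verify
the Monte-Carlo step against the closed-form Beta tail (two models) and an
independent sampler (three models); the variational posterior itself is an
approximation and is checked qualitatively (same modal model) against an
importance-sampling treatment of the exact posterior.

`baseline_validation()` asks, per subject, how often a *random* EV trace
fits the adjusted RTs better than the model under test: each repetition
draws an i.i.d. uniform $[0,1]$ trace (the simplest distribution consistent
with "random expected values" on the value scale; nothing downstream
depends on its shape beyond exchangeability), regresses and scores it, and
the per-subject p-value is the $+1$-corrected fraction of repetitions with
a lower baseline BIC — the correction keeps $p > 0$ strictly, which
Fisher's combination ($\chi^2 = -2\sum\ln p$ on $2m$ df) requires.

## Derived comparisons

`precision_vs_associability()` correlates the full learner's precision with
the Pearce–Hall associability on the same session. The package default for
the PH intensity in this diagnostic is 0.4 — a moderate, group-level fitted
value for this task class; at that value the mean correlation across
simulated sessions is weakly negative (about $-0.12$), i.e. the two
"uncertainty" signals are essentially unrelated, because precision moves
with *anticipated* structure while associability reacts to experienced
error. `bin_ev()` reproduces the reporting bins: a two-bin split at $+0.3$
(appetitive) / $-0.3$ (aversive), boundary values falling low, and an
empirical-tertile mode whose ties also break to the lower bin (a degenerate
all-equal trace collapses into the single low bin).

Correlations are computed per session and then averaged — never on
concatenated traces, which would mix between- and within-session variance.

## Problem sizes and what the tests show

The test suite and the acceptance script run entirely on synthetic data at
the study's own scale: 120-trial sessions, 19-session/19-subject cohorts,
200 sessions for the reinforcement-rate check, 500 unconstrained sessions
for the hazard check, grid searches at steps 0.001–0.05, and 50–200
repetitions for the validation statistics. These sizes keep every check
well-powered for the properties asserted (binomial standard errors of the
order $10^{-3}$–$10^{-2}$) while running in minutes on one core.

Passing tests show that the algorithms are internally correct (oracle
equivalences), that the generator realizes the stated protocol, and that
the full analysis chain recovers generating models and parameters from
synthetic RTs. They do not show that human RTs follow the log-linear
generative model, that real learners use these parameter values, or
anything about neural data: the synthetic RT model has exactly the
structure the fitting procedure assumes (plus noise), which makes
model-recovery results an upper bound on what real data could yield.

## Known limitations

* Filtering only — no forward–backward smoothing; beliefs at trial $t$ use
  outcomes up to $t$ only.
* $\alpha$ and $\beta$ are fixed per analysis, not estimated per subject;
  only the calibration diagnostic above constrains $\alpha$.
* The RT noise model is Gaussian on the log scale; no shifted-lognormal,
  drift-diffusion or contaminant-mixture variants.
* The two-state $S$ space omits the concurrent pleasant+unpleasant
  configuration (irrelevant under this protocol, where sessions are
  valence-pure).
* Exceedance probabilities are plain (not protected), and family-level
  selection is out of scope.
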