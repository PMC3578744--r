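# pavlovhmm

Trial-by-trial learning models for Pavlovian serial-reversal conditioning,
with a synthetic task generator, reaction-time-based model fitting, and
random-effects Bayesian model selection.

## The scientific problem

In a serial-reversal Pavlovian task, a participant watches pairs of cues: on
each trial one cue of the current pair is shown and is followed, with
probability 0.6, by delivery of a liquid — an affectively *valenced* liquid
(pleasant in the appetitive session, unpleasant in the aversive session) for
one cue, a neutral liquid for the other. After a minimum block of 16 trials,
a per-trial trigger with probability 0.25 fires either a *reversal* (the two
cues swap liquids) or the introduction of a completely new cue pair; each of
three pairs per 120-trial session reverses exactly once.

A *model-based* learner can exploit this structure: knowing that
contingencies reverse, it treats a reversal as resolution of uncertainty
rather than something to re-learn. The package implements such a learner as
a Bayesian hidden Markov model (HMM) and contrasts it with *model-free*
comparators that only chase prediction errors.

## The models

**HMM with dynamic reversal expectation.** A joint belief is maintained over
the contingency state *S* (which cue of the pair carries the valenced
liquid) and a binary reversal-expectation node *H*. *H* moves 0 → 1 with
probability α per trial and never returns; while *H* = 1 the state swaps
with probability β per trial. Beliefs are filtered forward through the
transition operators and conditioned on each cue–outcome observation
(emission probabilities 0.6 / 0.4). The expected value of presented cue *j*
is

&nbsp;&nbsp;&nbsp;&nbsp;Q<sub>j</sub> = Σ<sub>S</sub> P(S) · 0.6 · R(liquid of *j* under *S*),

with R = +1 / 0 / −1 for pleasant / neutral / unpleasant liquids, and the
*precision* of the state belief is the normalized negentropy
1 − H(P(S))/log₂K. A *reduced* HMM clamps *H* = 1 (constant hazard): its EV
trace is nearly identical to the full model's, but its precision lacks the
anticipatory decline between reversals.

**Model-free comparators.** Rescorla–Wagner (`Q ← Q + α(R − Q)`),
Pearce–Hall (associability = previous absolute prediction error;
`Q ← Q + S·assoc·R`), a Hybrid rule (RW value update with a PH-controlled
learning rate), and a constant baseline (EV ≡ 0.5).

**Fitting and selection.** Log RTs are adjusted for a linear trend and
side-switch costs; each model's EV trace is regressed against the adjusted
RTs (free parameters searched on a 0.001 grid), scored by
BIC = n·ln(SSE/n) + k·ln(n), and compared across subjects by random-effects
Bayesian model selection (posterior and exceedance probabilities from a
variational Dirichlet) plus a simulation-based baseline validation combined
across subjects with Fisher's method.

## Worked example

```r
library(pavlovhmm)

sess <- generate_session(task_config(), seed = 1)
sess
#> session_sequence: 120 trials, appetitive session, seed 1
#>   3 cue pairs, 3 reversals, 0.592 of trials reinforced

tra <- hmm_filter(sess)
round(tra$ev[1:5], 3)
#> [1] 0.3 0.3 0.3 0.3 0.3      # uniform prior: 0.5 * 0.6 * 1, until an
#>                              # informative outcome arrives

trace_correlation(tra$ev, reduced_hmm_filter(sess)$ev)
#> [1] 0.992                    # the reduced model's EVs are near-identical

rt <- simulate_rts(sess, tra$ev, rt_config(), seed = 2)
adj <- adjust_rts(rt, sess$trials$side)
fit_model_to_rts(adj, "HMM", sess)
#>   model best_param   sse   n k     bic
#>     HMM         NA 1.511 120 0 -524.94
```

With RTs generated from the HMM's expected values, the HMM attains the
lowest (best) BIC of all five models on this session (−524.9 vs −521.9 for
the baseline and −517.3 for the best model-free rule); `fit_sessions()`,
`bms_random_effects()` and `baseline_validation()` scale the same comparison
to a cohort, and `run_pipeline()` chains every stage and writes
`sessions.csv`, `traces.csv`, `fits.csv`, `bms.json`, `validation.json`,
`report.json` and a manifest.

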