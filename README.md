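# grlearn

Behavioral modeling of **generalized reinforcement learning (GRL)** on a
hierarchical reversal-learning task, for computational cognitive
scientists who want to simulate, fit, and stress-test choice models of
counterfactual generalization.

## The problem

In the task, four cues pair into two categories of two states each. Within
a category the two states always reward *opposite* actions, and this
hidden rule (the category's *metastate*, "AL/BR" vs. "AR/BL") reverses for
exactly one category at each block transition. A learner that understands
the structure can update values it never directly experienced: when
(state A, left) is rewarded, it can *discriminatively* infer that the
nonchosen action lost value (action generalization, weight `g_A ≤ 0`) and
that the complementary state rewards the complementary action (state
generalization, `g_S < 0`). A learner that wrongly treats the two states
as one instead *associatively* overgeneralizes (`g_S > 0`).

The core model extends temporal-difference learning of state values
`V(s0)` and action values `Q(s, a)` with counterfactual relays of the
outcome prediction error `δ_Q = r − Q(s_t, a_t)`:

```
Q(s ,a )  += α δ_Q                 (direct)
V         = f(V + λ α δ_Q)         (eligibility trace, λ = 0.5)
Q(s ,a')  = f(Q + g_A α δ_Q)       (nonchosen action)
Q(s',a )  = f(Q + g_S α δ_Q)       (complementary state)
Q(s',a')  = f(Q + g_S g_A α δ_Q)   (interaction)
```

with `f(x) = max(0, min(1, x))`, inside a softmax policy with temperature
`τ`, an exponentially decaying perseveration/alternation bias
(`β0`, `λ_β`), and a lateral bias `β_R`. Around the 7-parameter GRL model
sits a zoo of 20 models: ten nested GRL variants, an 8-parameter free
interaction, metastate belief learners (a delta-rule SPE learner and a
Bayesian hidden Markov learner with consistency `θ0` and reversal rate
`θ1`), dual-systems mixtures (`w_MB`), and hysteresis / intercept / chance
baselines. Models are fitted per subject by restarted Nelder-Mead maximum
likelihood and compared by AICc.

The package contains the complete pipeline: a seeded, audited task
generator with exact-count reward schedules; free-running and yoked agent
simulation; fitting, model comparison, learner/generalizer classification;
model and parameter recovery; the model-independent behavioral statistics
(first-generalization accuracy, conditional repeat probabilities,
psychometric choice/RT regressions); posterior predictive checks; and
TSV/JSON I/O including a trial-level regressor export for downstream GLM
use. See the methods vignette (`vignettes/grl-methods.Rmd`) for the full
model account.

## Worked example

```r
library(grlearn)

session <- generate_session(task_config(seed = 7))
session
#> grl_session: 384 trials, 12 blocks, 4 runs (variant 3FH, seed 7)
#> scheduled rewards: 240 (left-action yield 120)

# a strongly discriminative generalizer
rec <- run_agent(session, "AX|SY",
                 c(alpha = 0.5, g_a = -0.7, g_s = -0.8, tau = 0.3,
                   beta0 = -0.1, lambda_beta = 0.5, beta_r = 0.1),
                 seed = 8)
record_accuracy(rec)
#> 0.745
first_generalization_accuracy(rec)
#> $accuracy 0.875; $n_trials 16

fit <- fit_mle(rec, "AX|SY", n_restarts = 10, seed = 1)
fit
#> grl_fit AX|SY: NLL 165.82, AICc 345.94 (df 7, n 384)
#>  alpha 0.4502  g_a -0.7641  g_s -0.8458  tau 0.2811 ...
classify_generalizer(fit)
#> "Discriminative"
reward_sensitivity(fit$params)
#> 1.651

hyst <- fit_mle(rec, "hysteresis", n_restarts = 10, seed = 1)
hyst$aicc - fit$aicc   # AICc residual vs. the outcome-insensitive baseline
#> 182
```

The session audit (`session$audit`) verifies the design guarantees: 384
trials in 12 blocks, quartet structure with no repeated cue on consecutive
trials, exact scheduled counts in sixteenths, a constant-action yield of
exactly half the 240 scheduled rewards, exact per-run reward quarters, and
one category remapped per block transition. The agent's 16
first-generalization trials are the purest probe of generalization: the
first encounters with a complementary state after the category's first
reward under a new mapping.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic
cohorts and write tables under `results/`:

1. `01_generate_task.R` — design generation and audit
2. `02_simulate_cohorts.R` — discriminative / associative / basic-RL cohorts
3. `03_fit_models.R` — zoo fitting, AICc comparison, classification
4. `04_model_recovery.R` — complex-from-complex, simple-from-simple
5. `05_parameter_recovery.R` — truth-vs-estimate correlations
6. `06_behavior_ppc.R` — psychometrics and the posterior-predictive
   falsification of basic RL

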