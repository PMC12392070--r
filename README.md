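# decaytd

Simulators for temporal-difference (TD) reinforcement-learning models of
the dopamine–striatum system in which learned values decay over time.

Dopamine recordings across striatal regions show qualitatively different
patterns: abrupt phasic responses at a reward-predicting cue in some
regions, ramps toward the reward in others; day-scale forgetting in some,
long-term retention in others; and regional differences in how well
neural activity encodes the reward *distribution* versus its *mean*.
`decaytd` is for computational neuroscientists who want to regenerate and
probe, at desk scale, a family of models in which one ingredient —
multiplicative decay of learned values or value weights — interacts with
the state representation and circuit architecture to produce all of these
patterns.

## Models

All models learn on an internally generated Pavlovian cue–delay–reward
task (states $S_1,\dots,S_n$, reward only at $S_n$) from the TD
reward-prediction error (RPE)

$$\delta_i = R_i + \gamma V(S_{i+1}) - V(S_i),$$

with value decay $V \leftarrow (1-\kappa)V$ applied at every within-trial
time-step. The package implements:

- **Tabular TD with decay** (`run_punctate()`): each within-trial timing is
  its own state; decay produces a ramping RPE toward reward.
- **Linear-feature TD** (`run_feature_td()`): values
  $V = w\cdot x - w_0\sum_j x_j$ with non-negative weights, asymmetric
  learning rates, and weight decay toward baseline, under sparse, dense,
  successor (SR) and predecessor (PR) representations — the degree of RPE
  ramping falls with feature overlap.
- **Online SR learning** (`run_navigation()`): the representation itself is
  learned by feature-level TD during a simulated navigation task, making
  the RPE ramp fade across sessions.
- **Online value-RNN** (`run_ovrnn()`): a 40-unit recurrent network and its
  value readout trained simultaneously by the same RPE with random
  feedback; value-weight decay removes the cue peak only for dynamic cues
  with short inter-trial intervals.
- **Hierarchical two-circuit model** (`run_hierarchical()`): a fast,
  decaying circuit M drives a slow, non-decaying circuit L through
  conditioned reinforcement, dissociating forgetting from retention across
  learning, rest and extinction phases.
- **Distributional RL** (`run_distributional()`): D1/D2 pathway values with
  opposite learning-rate asymmetries under a shared ("integRPE") or
  per-pathway ("segreRPE") RPE, plus distribution- and mean-coding strength
  metrics (`distribution_coding_score()`, `mean_coding_score()`).

Configuration-driven experiment presets tie these together
(`experiment_presets()`, `run_experiment()`), writing long-format CSV
tables plus a JSON sidecar with the resolved configuration and seed.

## Worked example

Tabular TD on the 5-state task, 200 trials, learning rate 0.15, decay rate
0.01 — the steady-state profile of the final trial:

```r
library(decaytd)
task <- make_task(n_states = 5, reward_schedule = list(c(1, 1)),
                  n_trials = 200, gamma = 1)
trace <- run_punctate(task, a = 0.15, kappa = 0.01)
round(steady_profile(trace), 3)
#>   step delta value
#> 1    0 0.238 0.000
#> 2    1 0.082 0.238
#> 3    2 0.109 0.316
#> 4    3 0.145 0.421
#> 5    4 0.192 0.560
#> 6    5 0.256 0.744
```

Step 0 is the cue-response channel (the RPE at an implicit zero-valued
pre-cue state, i.e. $\gamma V(S_1)$). With decay, the cue response is
effectively discounted (0.238 rather than 1) and the RPE *ramps* from 0.082
at the cue up to 0.256 at the reward, even though the reward is fully
predictable — without decay (`kappa = 0`) the same call leaves a cue
response of 1 and all within-trial RPEs at 0. The `value` column shows the
accompanying state-value ramp.

The two-circuit model dissociates forgetting from retention. Cue responses
(circuits M and L) at the end of 200 learning trials, and again at the
first extinction trial after a duration-matched rest:

```r
hier <- run_hierarchical()
round(cue_response(hier, "learning", "last"), 3)
#>     M     L
#> 0.408 0.452
round(cue_response(hier, "extinction", "first"), 3)
#>     M     L
#> 0.000 0.249
```

Circuit M (fast learning, value decay) has forgotten the cue value during
the rest period; circuit L (slow, no decay, fed by M's conditioned
reinforcement) retains 55% of its response.

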