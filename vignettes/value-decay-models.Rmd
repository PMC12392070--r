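---
title: "Value decay in TD-learning models of dopamine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value decay in TD-learning models of dopamine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decaytd)
```

## The problem

Dopamine responses recorded across the striatum do not follow a single
template. In some regions dopamine shows an abrupt, phasic burst at a
reward-predicting cue and little activity afterwards; in others it ramps up
toward the time of reward; some regions forget learned responses within a
day while others retain them over weeks. `decaytd` implements a family of
temporal-difference (TD) learning models in which a single mechanistic
ingredient — *decay of learned values* (or of the synaptic weights that
store them) — interacts with the state representation and the circuit
architecture to produce this diversity. Every model runs on the same
internally generated Pavlovian cue–delay–reward task, and every figure-scale
result is regenerated by simulation at desk scale.

## Task model

A trial consists of `n_states` within-trial states $S_1, \ldots, S_n$
entered at consecutive time-steps; $S_1$ is the cue and reward is delivered
only at $S_n$ (`make_task()`). The default protocol uses $n = 5$, 200
trials, reward size 1, and discount $\gamma = 1$; probabilistic variants
draw the reward size per trial from a two-point schedule (e.g. 1 or 3 with
equal probabilities). The generator emulates only the event structure of a
trace-conditioning task: there is no sensory noise, no variable cue–reward
delay, no action selection, and (outside the recurrent-network model) no
inter-trial interval. Passing tests therefore demonstrate properties of the
learning rules under idealized state sequences, not robustness to the many
sources of variability in real behavioral data.

For the recurrent-network model the task is instead a continuous time
series of 5-dimensional binary observations (`make_observation_stream()`):
4 cue steps (one unit held active for a *fixed* cue, units 1–4 in sequence
for a *dynamic* cue), a reward step (unit 5), and a silent inter-trial
interval (ITI) drawn uniformly from $\{4,5,6,7\}$ steps (*short*) or
$\{7,9,11,13\}$ (*long*). The ITI is counted exclusively — the number of
silent steps strictly between the reward step and the next cue-onset step —
which makes the listed values exact; this convention is fixed in the code.

## Learning rules

**Tabular TD with value decay** (`run_punctate()`). Each state carries its
own value ("punctate" representation).
$\delta_i = R_i + \gamma V(S_{i+1}) - V(S_i)$ (terminal state: the
upcoming-value term is dropped), $V(S_i) \mathrel{+}= a\,\delta_i$ with
$a = 0.15$, then *all* values decay, $V \leftarrow (1-\kappa)V$, once per
within-trial time-step, with $\kappa \in \{0, 0.01, 0.02\}$. Decay acts only
during task trials. The within-step order — compute the RPE, update the
visited state, decay everything — follows the order in which the operations
are defined; reported RPEs are always pre-update.

**Linear-feature TD** (`run_feature_td()`). States are feature vectors
$x_i$ and the value is $V(S_i) = w \cdot x_i - w_0 \sum_j x_{i,j}$ with all
stored weights clamped non-negative and initialized to the baseline
$w_0 = 0.5$; the subtraction lets effective weights go negative while
stored weights cannot (a stand-in for feedforward inhibition). The update is
$w \leftarrow \max(0, w + a_f\,\delta\,x_i/\lVert x_i\rVert^2)$ with
$a_+ = 0.15$ for non-negative and $a_- = 0.075$ for negative RPE, and decay
pulls weights back toward the baseline:
$w \leftarrow w_0 + (1-\kappa)(w - w_0)$. Representations: *sparse*
(100-dimensional, 10 random nonzero entries, unit norm), *dense* (all 100
entries positive, unit norm), *successor* (SR, $x_{i,j} = \gamma^{j-i}$ for
$j \ge i$) and *predecessor* (PR, its time-reversed analogue), both built
with $\gamma = 1$ independent of the value-learning discount. The degree of
RPE ramping under decay falls with the overlap between feature vectors
(sparse > dense > SR $\approx$ 0), and PR ramps down instead — the package's
acceptance tests check exactly this ordering.

**Online SR learning during navigation** (`run_navigation()`). The
navigation experiment is the same 5-state task (reward 1 or 0.5); the
representation starts punctate and each visited state's feature row is
updated by a feature-level TD error
$\delta^{SR}_i = I_i + \gamma x_{i+1} - x_i$ with $a_{SR} = 0.001$, 360
trials split into 9 sessions of 40. The interleaving of the feature update
and the value update within a time-step is not dictated by the update
equations themselves; the default updates features first (so the value step
sees the newest representation), and the `order` argument switches to the
reverse. At $a_{SR} = 0.001$ the two orderings differ only at second order;
the fading-ramp result holds under both.

**Online value-RNN** (`run_ovrnn()`). A 40-unit sigmoidal RNN
($x(t{+}1) = f(Ax(t) + Bo(t))$) feeds a linear value readout
$v = w^\top x$; both are trained online by the same RPE
$\delta(t) = r(t) + \gamma v(t{+}1) - v(t)$ with $\gamma = 0.8$,
$a_{RNN} = 0.1$, $a_{value} = 0.03$. Backpropagation's symmetric feedback is
replaced by fixed random gains $c_i \in [0,1]$, and the postsynaptic factor
$x(1-x)$ saturates at 0.25 above $x = 0.5$ (the two branches meet at 0.5, so
the rule is continuous). Value weights are clamped non-negative and decay
toward zero at rate `dr` (0 or 0.001) at *every* step, including ITIs —
learning is continuous across trials, unlike in the trial-episodic modules.
Because $\delta(t)$ needs $v(t{+}1)$, all updates for time $t$ are applied
after stepping to $t+1$, and the recurrent/feedforward update for
$\delta(t)$ uses presynaptic activities at $t-1$ and postsynaptic at $t$,
matching the index pattern of the update rules. The number of training
trials is a free parameter here; the package defaults to 1,000 trials with
reported profiles averaged over the last 100, which comfortably exceeds the
representation-learning timescale at $a_{RNN} = 0.1$ while keeping a
100-repetition condition sweep fast. The per-step training loop is compiled
(Rcpp) for speed; a step-by-step R reference built from the exported
primitives is tested against it to machine precision.

**Hierarchical two-circuit model** (`run_hierarchical()`). Circuit M (fast:
$a_M = 0.25$, $\kappa_M = 0.01$) receives reward directly; circuit L (slow:
$a_L = 0.025$, $\kappa_L = 0$) receives no reward input — its RPE is driven
by the upcoming-state value relayed from M (conditioned reinforcement):
$\delta_{L i} = \gamma(0.5 V_L(S_{i+1}) + 0.5 V_M(S_{i+1})) -
\lambda_{cur} V_L(S_i)$. With $\lambda_{cur} = 1$ the effective discount is
1 in the *presence* of the M input; the revised variant
$\lambda_{cur} = 0.5$ makes it 1 in its *absence*, which softens the
negative extinction transient and lets circuit L amplify value toward the
cue (its converged profile obeys the backward recursion
$V_L(i) = V_L(i{+}1) + V_M(i{+}1)$). Phases run in sequence: learning
(reward per schedule), rest (decay only, applied
$n_{states} \times n_{trials}$ times, the duration-matched equivalent of
that many trials), extinction (reward forced to 0). Both circuits compute
their RPEs from pre-update values, then update, then decay — synchronous
circuits; at these learning rates cross-circuit ordering effects are second
order. Whether circuit L should see M's values *as they decay during
extinction* is not determined by the model equations; under the shared loop
implemented here it does.

**Distributional RL** (`run_distributional()`). Two pathway value vectors
$V_1$ (D1) and $V_2$ (D2) learn with opposite asymmetries
$(a_{1+}, a_{1-}, a_{2+}, a_{2-}) = (0.15, 0.05, 0.05, 0.15)$. *integRPE*
computes one RPE from the summed values and feeds it to both pathways: only
$V_1 + V_2$ is constrained, so the pathway values drift apart without bound
unless decay ($\kappa = 0.01$) is added. *segreRPE* computes per-pathway
RPEs; each pathway then converges to an expectile-like statistic of the
reward distribution (for reward 1 or 3 with equal probabilities: 2.5 and
1.5, the asymmetric fixed points solved independently by root finding in
the tests), needs no decay, and is distorted by it.

## Coding-strength metrics

`distribution_coding_score()` adds Gaussian noise (SD 0.05 or 0.07) to the
(D1, D2) values of paired simulations of a "fixed" (always 2) and a
"variable" (1 or 3) condition, forms per-time-step difference vectors in
the (D1, D2) plane, and averages the cosine similarity over all
$1000 \times 999 / 2 = 499{,}500$ unordered pairs. Zero-length difference
vectors would make the cosine undefined; they are excluded and counted
(none occur at the protocol's noise levels). `mean_coding_score()`
z-normalizes noisy D1 (and separately D2) values across three conditions
with reward means 0, 2, 2, and reports the per-time-step $R^2$ of a
regression of the reward mean on the normalized pair. Three choices here
were genuinely open and are fixed as follows: values are taken from the
*last trial* of each 200-trial simulation (the trial count and snapshot are
not dictated by the protocol; 200 trials is past the learning transient for
both algorithms); normalization is per simulation *and per time-step*
across the three condition values; and "$R^2$ of correlation" with two
predictors is read as the multiple-regression $R^2$
(reward mean ~ normalized D1 + normalized D2), with the average of the two
univariate $R^2$s available via `method = "average_univariate"`. Noise is
added only after the values are generated — it never feeds back into
learning.

## Numerical conventions

*Cue response.* The RPE formula yields no cue transient at steady state (at
$S_1$, $\delta_1 \to 0$), yet an abrupt cue response is a central model
output, and the delay-sweep experiment equates the cue value with the RPE
upon cue. All trial-based runners therefore model an implicit pre-cue state
with permanently zero value that is never updated: the step-0 channel of
every trace reports $\gamma V(S_1)$ (for circuit L, the discounted value
composite entering its own RPE). At $\gamma = 1$ — everywhere except the
discounting comparison — this equals $V(S_1)$, so the two candidate
conventions are indistinguishable; `cue_response = "value"` switches to the
undiscounted variant.

*Steady state.* "After learning became almost steady" is operationalized as
the final trial (configurable to the mean of the last $K$ trials via
`steady_profile(last_k = )`). Deterministic runs converge geometrically; the
test suite checks the 2,000–3,000-trial state against independent
iterate-to-convergence solvers at $10^{-8}$.

*Degenerate inputs.* `n_states = 1` collapses cue and reward into one state
and is exercised in the tests; schedules must sum to probability 1 to within
$10^{-8}$; decay rates must lie in $[0, 1)$.

*Randomness.* Every stochastic function takes a `seed` argument and seeds a
local RNG (via `withr`), so no call disturbs the caller's RNG state and
every trace is bit-reproducible from `(config, seed)`. The compiled RNN
loop consumes no random numbers — all draws happen in R.

## Problem sizes

The shipped tests and the acceptance script run the protocols at their
native scales — 200-trial learning runs, 100 repetitions for random feature
draws and for the RNN condition sweep, 2,000-trial distributional runs, and
1,000 paired simulations per condition for the coding metrics — since the
whole suite completes in about a minute on a single core. The RNN sweep is
the only computation that benefits from the compiled core.

## Known limitations

- State transitions are passive and deterministic; there is no
  actor/action-value learning, no spatial geometry in the navigation
  abstraction, and no distinction between stimulus- and action-driven
  transitions.
- Value decay outside task trials is modeled only in the RNN module (where
  learning is continuous); the trial-based modules decay only within trials.
- The distributional module uses single D1/D2 units with one asymmetry
  each, not graded populations, and D2 values are stored sign-true rather
  than sign-reversed.
- The two-circuit model does not account for responses to never-rewarded
  stimuli, saliency coding, or generalization across stimuli.
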