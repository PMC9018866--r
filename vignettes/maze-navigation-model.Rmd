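---
title: "Belief filtering and pattern decoding for partially observable maze navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief filtering and pattern decoding for partially observable maze navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazenav)
```

## The task and its state space

An agent explores a rectangular grid maze in which every pair of adjacent
cells shares a door that is open or closed; boundary walls are closed. The
hidden *state* $h$ is the agent's cell plus facing direction (a 5×5 maze has
100 states). The agent observes only the egocentric *scene* $o$: the
open/closed status of the doors to its left, forward and right, encoded as a
3-bit label $4\,\mathrm{left} + 2\,\mathrm{forward} + \mathrm{right}$. A cell
whose three visible doors are all closed would be a dead end, so label 0
never occurs and exactly seven scene types exist. Valid mazes additionally
require every cell to have at least two open doors, full connectivity, and
*partial observability*: every realized scene is shared by at least two
states, so a single observation never identifies the state.

Each game starts at an unknown state. On an *action trial* the agent sees
the current scene and moves left, forward or right; choosing a closed door
is a no-op that re-presents the same scene. After 1–5 action trials a
*prediction trial* occurs: before seeing the next scene, the agent reports a
four-level confidence and then picks the upcoming scene from four options
(the true scene plus three distractors drawn from scenes reachable by the
same action from states showing the previously observed scene). A game ends
when the agent first visits a novel state after at least five completed
prediction trials.

## The behavioral model

The model tracks a joint cognitive state per trial: the state estimate $h_t$,
a binary *state confidence* $c_t$, an *operant mode* $m_t$, and the set of
grid cells the agent believes it has visited. Action selection switches
between two strategies according to $c_t$:

* **Forward-dominant** (low confidence): move forward if possible; if
  forward is closed and both side doors are open, prefer right; a single
  open door is taken with probability one. The optimal action has
  probability $\alpha$, and each other passable action
  $(1-\alpha)/N_\mathrm{nopt}$.
* **Efficient exploration** (high confidence): all passable doors into
  unvisited cells are optimal; if every accessible neighbor was visited, the
  optimal actions are those starting a shortest open-door path (breadth-first
  distance on the cell graph) to the nearest unexplored cell. Optimal
  actions share probability $\beta$, the rest share $1-\beta$, and the mass
  renormalizes when no passable non-optimal action exists. The path search
  runs on the undirected cell graph; facing direction is ignored at this
  stage, which is the natural reading of a "shortest path to the nearest
  unexplored grid" and keeps the policy independent of how the agent would
  turn along the way.

After each move the predicted scene (from pushing $h_t$ through the action)
is compared with the observation. A match is an *update*: the state estimate
moves deterministically and low confidence switches high with probability
$p_{L\to H}$ (high stays high). A mismatch is a *backtrack*: the estimate is
discarded and re-drawn uniformly from the states consistent with the recent
observable window, and high confidence switches low with probability
$p_{H\to L}$ (low stays low). Two exceptions keep the bookkeeping coherent:
a confirmed move into an already-visited, different cell counts as an
*action backtrack* (backtrack confidence dynamics, but the confirmed state
update is kept — there is no observational discrepancy to resolve; a switch
`action_backtrack_resamples` restores full re-estimation); and if every
passable door led to a visited cell, the revisit was unavoidable and the
step is a *forced update* (update dynamics).

The re-estimation window covers the last $n$ actions (including the current
one) together with their aligned scenes, ending at the current observation.
The quoted indexing of the window in the source description is ambiguous
about whether the current observation is inside or in addition to the
$n$-step count; we implement $n$ action steps plus the terminal scene,
isolated in one function, so the alternative is a one-line change. A
hypothesized trajectory must also reproduce the observed success or failure
of every move — a failed move is observable, because the chosen door is
visibly closed in the matching scene.

## Exact filtering

The experimenter-side filter maintains a weighted set of hypotheses
$(h, c, \text{mode}, V)$, where $V$ is the subjective visited-cell set; $V$
is part of the hypothesis key because both the efficient-exploration policy
and the action-backtrack exception depend on it. One step conditions on the
observed action (each hypothesis's likelihood is the probability its
confidence-appropriate strategy assigns to that action) and then branches
every hypothesis through the observed outcome: two confidence branches, and
for backtracks a uniform branch over the window-consistent states with the
visited set reset to the cells traversed by the consistent trajectories
(`visited_reset = "window"`; `"keep"` and `"clear"` are available). The
per-step predictive action probability — the model-evidence factor — is
recorded before renormalization; hypotheses with identical keys are merged
and weights below $10^{-8}$ (relative) are pruned.

Numerical and degenerate-input choices: visited sets are 32-bit masks, so
mazes are limited to 30 cells (the study-scale maze has 25); when no
surviving hypothesis allows the observed action (e.g. a choice of a visibly
closed door, which the policies give probability zero), the evidence factor
is floored at $10^{-10}$ and the belief is carried through unchanged rather
than raising an error; argmax read-outs break ties to the lowest scene label
or state index; the binary state-confidence read-out compares the largest
joint mass $P(c{=}1, h)$ over the maximal-marginal states against the total
mass at $c{=}0$, with exact ties reported as low.

The filter exists twice: a readable R reference built from `step_filter()`,
and a compiled whole-game path used by the evidence and fitting code. The R
path is certified against an exhaustive trajectory-enumeration oracle (no
merging, no pruning, independent set bookkeeping) on 3×3 mazes to
$10^{-10}$, and the compiled path is asserted equal to the R path on
simulated study-scale logs.

## Fitting and model comparison

The evidence of a subject's log is the product of per-action predictive
probabilities over all games (prediction trials contribute no likelihood;
the data are the action sequences). `fit_subject()` minimizes the negative
log evidence with a seeded multi-start Nelder–Mead search on
logit-transformed parameters bounded to $[0.01, 0.99]$ (the box keeps the
log evidence finite at the edges), crossed with an exhaustive grid over the
window length $n$. The grid default is $1..3$: the window only matters at
backtrack events, longer windows are rarely distinguishable at desk scale,
and each additional value costs a full continuous search; `n_max` is an
ordinary argument for users who want more. AIC counts $n$ as a free
parameter since it is fitted (a flag restores the alternative convention);
the switching model has 5 free parameters, each single-strategy variant 2.

A caveat worth stating: with 30 games per subject, $n$ and $p_{H\to L}$ are
weakly identified, because both matter only at backtrack events and
specifically at backtracks from high confidence, which are rare. The
recovery harness in the tests measures exactly this, and with large game
counts the evidence concentrates on the generating $n$, so the weakness is a
property of the data volume, not of the estimator.

## Synthetic subjects

`simulate_subject()` runs the model generatively in the single-sampled-
hypothesis reading: the initial estimate is drawn uniformly from the states
consistent with the first scene, actions are sampled from the
confidence-appropriate strategy, and backtracks re-draw the estimate from
the window-consistent set. Two report-level noise models — deliberately not
part of the cognitive model, and isolated in `agent_spec()` — turn the
hidden binary confidence into a four-level report (the reported side matches
the internal one with probability `report_fidelity`, default 0.85, with a
configurable level split within each side) and produce scene-choice reaction
times (base 1.8 s, minus 0.3 s at high-confidence reports and 0.15 s on
correct choices, Gaussian noise with sd 0.4 s, truncated at 0.2 s — values
chosen once as plausible for a 4.5 s response window). Misses (0.7%) and
computer-chosen timeout actions (2.8%) are injected at the task layer at the
rates of the scanner protocol.

What the generator does *not* emulate: imperfect memory of the maze layout
(every synthetic subject knows the map exactly, so prediction accuracies are
substantially higher than human ones), learning or forgetting across
sessions, and any within-trial deliberation dynamics. Passing behavioral
checks therefore show that the pipeline recovers the effects its own model
produces, not that humans behave like the model.

## Synthetic activity patterns

`generate_patterns()` gives every non-missed prediction trial a 9-period
feature series: a unit-norm prototype of the *chosen* scene (pairwise
prototype correlations bounded below 0.3), scaled by a temporal envelope
peaking at period 6 and a global amplitude, plus a per-session feature drift
and Gaussian noise whose standard deviation depends on confidence (defaults
0.5 at high, 1.0 at low). Confidence modulating the noise rather than the
signal follows the variability reading of why high-confidence trials should
decode better; since trial-mean data cannot distinguish the two mechanisms,
an amplitude-modulation mode is provided (`conf_modulates = "amplitude"`).
By default the modulation is driven by the simulator's hidden confidence —
the common cause of both the reported and the model-estimated labels — so
both conditional analyses see the effect. Features are finally z-scored per
session, emulating run-wise voxel normalization. Setting `amplitude = 0`
produces label-free data and is the basis of the calibration checks.

## Decoding

The decoders are L1-penalized logistic one-vs-rest classifiers (glmnet),
i.e. sparse probabilistic linear classifiers with automatic feature
selection; the predicted label is the argmax of the per-class probabilities,
ties to the lowest label, and a two-class target uses a single binary
classifier. The penalty is chosen per classifier on a stratified internal
split of the *training* data only (log-loss over a 25-value path), or can be
fixed. Cross-validation leaves out one session (LOSO) or one game (LOGO);
within each fold the training set is undersampled to balanced classes,
trained, and evaluated on the untouched test fold, repeated (100 times at
full scale) and averaged. Test folds never enter undersampling, penalty
selection, or training. Conditional decoders filter trials to one condition
(correctness, reported confidence side, or model state-confidence side) and
use LOGO; subjects with fewer than 3 training samples of any label in any
fold are excluded with a machine-readable reason (an effective floor of 2
applies everywhere, since a classifier cannot be trained on a single-sample
class). Condition contrasts use one-sided Wilcoxon rank-sum tests on
per-subject accuracies, as do the behavioral two-group comparisons; with a
single two-group comparison no multiplicity correction is applied.

The two-step permutation test permutes the target labels within sessions
per subject ($N_\mathrm{sbj}$ times, re-decoding each), then builds
$N_\mathrm{group}$ group-level null values by drawing one entry per subject
from the pools (original included) and averaging; the original per-subject
accuracies are compared against the null with a one-sided rank-sum test.
Full-scale settings are 150/1000; the package defaults to the scaled 30/200
for routine runs, with the full setting one argument away.

One structural property of this scheme deserves a warning. The final
comparison sets per-subject *individual* accuracies against a null
distribution of *group means*; under the null hypothesis the means are
roughly $\sqrt{S}$ times narrower than the individual values, so the
rank-sum test's variance assumption is violated and its type-I error runs
above the nominal level, increasingly so for larger cohorts. The
calibration check in the test suite measures exactly this rejection rate on
label-free data, and the package reports the null distribution and pools so
users can apply a percentile test of the group-mean accuracy instead, which
is calibrated by construction.

## Verification scale

The shipped checks run at sizes chosen to exercise the study conditions on
one CPU: exact-filter certification on 3×3 mazes with 6-step windows;
parameter recovery and model selection on 20 synthetic subjects × 30 games
at $\theta = (0.9, 0.85, 0.4, 0.5, n{=}2)$; behavioral effects on that same
cohort; decoder calibration on amplitude-0 data at 120 features with 10
undersampling repeats; null calibration of the permutation test over 100
synthetic null cohorts at 30/200; and the confidence-modulated decodability
contrast on 15 subjects × 10 games with a noise-sd ratio of 2. Full-scale
settings (600 features, 100 repeats, 150/1000 permutations, 40 games) are
the documented defaults of the corresponding constructors.

## Known limitations

The maze generator rejection-samples i.i.d. Bernoulli(0.55) doors with
repair passes, which matches the structural constraints but not any
particular hand-crafted layout; mazes beyond 30 cells are unsupported by the
filter's bitmask bookkeeping; the window length is weakly identified at
realistic data volumes (above); and the synthetic cohort's accuracy ceiling
compresses the low-confidence tail relative to human data, which makes some
conditional decoders drop subjects for want of low-confidence trials —
exactly as the exclusion rules intend.
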