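---
title: "Scene-gated value learning in the striatum tail: model, assumptions, and what the circuit can and cannot do"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scene-gated value learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenegate)
```

## 1. The scientific setting

Objects do not have fixed values: the same object can predict a large reward
in one environment and a small one in another. In the primate striatum tail
(CDt/PUTt), output neurons (medium spiny neurons, MSNs) carry stable
long-term object values, and a circuit hypothesis attributes the
*environment-dependence* of those values to fast-spiking interneurons
(FSIs): FSIs are excited scene-selectively and inhibit MSNs, so each MSN
effectively learns object values under the scene in which it is least
inhibited. Two mirrored MSN groups (scene X-preferring and scene
Y-preferring) then feed a disinhibitory pathway (MSN ⊣ SNr ⊣ SC) whose
combined output biases saccades toward the currently good object in either
scene. Pharmacologically silencing the FSIs' excitatory drive before
learning abolishes scene-based learning; doing so after learning leaves the
behaviour intact, which is attributed to learned scene-selective excitatory
input onto the MSNs themselves.

`scenegate` implements this hypothesis as an executable model, plus the task
environments, behaviour metrics and spike-train analyses needed to treat it
exactly like an experimental preparation.

## 2. The plasticity model

One model MSN holds unitless synaptic weights for each object and each scene
and a fixed FSI input magnitude per scene. On presentation of (at most) one
object and one scene, the response is

$$\mathrm{MSN} = \sum_o I_o S_o + \sum_s I_s S_s - \sum_s I_s \mathit{FSI}_s,$$

and each presented element's weight then moves by

$$S_e \leftarrow S_e + I_e \cdot \mathrm{MSN} \cdot \mathit{Reward} \cdot \mathit{LS}.$$

Parameters and their defaults:

| parameter | default | meaning |
|---|---|---|
| $S_o, S_s$ at start | 1 | initial synaptic weights (unitless) |
| $\mathit{LS}$ | 0.01 | learning-speed coefficient |
| $\mathit{Reward}$ | +1 / −0.5 | teaching signal for large (0.3 mL) / small (0.1 mL) reward; a task-configuration field |
| $\mathit{FSI}$, normal | (0.6, 1) and (1, 0.6) | mirrored scene X- and Y-preferring units |
| $\mathit{FSI}$, low-FSI | (0.5, 0.5) | scene-selectivity removed (the blockade analogue) |

Assumptions worth making explicit:

* **Trial resolution.** The model is defined per trial; within-trial timing
  (800 ms scene, fixation, 400 ms object epochs) is task metadata only.
* **Two mirrored units.** Only one unit's FSI magnitudes are published; the
  second unit's (1, 0.6) is a mirror assumption. The population readout
  needs both groups.
* **Response-contingent updates.** In the choice task the chosen object
  (plus the current scene) drives the update; the unchosen object's weight
  is untouched. An `update_policy = "offered"` switch treats both offered
  objects as presented, but then both object weights receive the *same*
  increment (the printed rule has a single MSN × Reward term per trial), so
  object differentiation is impossible under it; we default to chosen-only.
* **Unclamped weights.** Weights may go negative; an optional `floor`
  argument exists for exploratory use.

### 2.1 The sign of the inhibition term

The typeset response equation contains a division symbol before the FSI
terms. We provide both readings and default to subtraction:

* `inhibition = "subtractive"` (default) matches the worked arithmetic that
  the model's published parameters imply (initial response to object A in
  scene X: $1 + 1 - 0.6 = 1.4$; one rewarded update: $S_{OA} = 1.014$; one
  small-reward update: $0.993$), and matches the verbal description of FSIs
  as inhibitory inputs summed against excitation.
* `inhibition = "divisive"` reads the glyph literally as shunting-style gain
  control: the excitatory sum divided by the FSI pool. This reading is
  biologically respectable and, notably, is *scale-free*: the relative
  advantage of the preferred scene survives weight growth, whereas the
  subtractive version's fixed 0.4 offset becomes negligible as weights grow.

Section 5 shows that the distinction matters for what the circuit can
express, and why we nevertheless keep subtraction as the default.

### 2.2 Rectification

The printed equations are linear, so `rectify = FALSE` is the default
everywhere. `rectify = TRUE` clamps responses (and the response factor in
updates) at zero, modelling the fact that strongly hyperpolarised MSNs emit
no spikes. Rectification is the only nonlinearity available to the readout,
and Section 5 shows that several claimed behaviours would *require* it to
bind — which the published initial conditions prevent.

## 3. The readout and policy layer

The SC drive of an offered object is the sum over units of their activation
to (object, scene) — a monotone aggregate standing in for the monotone
double-inhibition MSN ⊣ SNr ⊣ SC, for which no equations are published.
Choices are drawn by an explicit policy layer that is *our* construction,
not the paper's: softmax on the drive difference
($P(o_1) = 1/(1+e^{-\beta(d_1-d_2)})$, $\beta = 5$ by default) or
ε-greedy argmax. The default β was calibrated so that an agent that *can*
discriminate the offered values (the no-scene task) converts its learned
drive differences into reliably correct choices within one session; β is a
configuration field and is never hard-coded in analyses.

## 4. Task environments and the synthetic-data generator

`task_config()` encodes the three behavioural procedures: the two-object and
eight-object scene-reversal tasks and the fixed-value no-scene task
(rewards 0.3/0.1 mL; 160-trial sessions; block length 20). Block-mode
sessions change scene at every 20-trial block boundary (with two scenes,
alternation from a random start), so a 160-trial session always contains
8 scene runs and switch-aligned metrics are defined on every session;
random mode draws the scene independently each trial. Every trial offers one
currently good and one currently bad object drawn uniformly, in randomised
screen order. `passive_schedule()` builds probe sessions with every
(scene, object) cell presented exactly `reps ≥ 7` times.

`synthetic_unit()` generates the recordings the ephys pipeline consumes: a
smooth biphasic waveform (two opposed Gaussian lobes) whose peak-to-trough
time equals the target within one 25 µs sample, and an
inhomogeneous-Poisson spike train with the stated baseline rate and a rate
step in the 50–400 ms post-object window. What it deliberately does *not*
emulate: real scene images or fractal objects (labels only), saccade
kinematics, bursting or refractory spike statistics, waveform noise, or any
quantitative TAN firing model (TAN status is an annotation). Passing tests
on these fixtures therefore validate the analysis code, not the
physiological realism of the fixtures.

## 5. What the circuit can and cannot do: a structural analysis

This package's virtual experiments treat the model's claimed behaviours as
falsifiable predictions. Two of them fail for structural reasons that are
worth deriving, because they are properties of the published model, not of
this implementation.

### 5.1 Subtractive inhibition cannot express scene-conditional choice

With subtractive inhibition and no rectification, the drive difference
between the two offered objects under scene $s$ is

$$d(A \mid s) - d(B \mid s)
  = \sum_u \left[(S^u_{OA} + S^u_s - \mathit{FSI}^u_s) -
                 (S^u_{OB} + S^u_s - \mathit{FSI}^u_s)\right]
  = \sum_u (S^u_{OA} - S^u_{OB}),$$

in which every scene term cancels. The choice probability is therefore the
same in both scenes *at every possible weight configuration*: no amount of
training, under any policy, can make the agent prefer A in scene X and B in
scene Y. Rectification could break the cancellation, but only if some unit's
total input went negative — and starting from weights of 1 with
$\mathit{FSI} \le 1$ and rewards $\{+1, -0.5\}$, responses begin at 1.0–1.4
and the reward asymmetry drifts weights upward, so the clamp never binds.
Scene-conditional choice is thus unreachable under the published
parameters. This is why the acceptance checks for within-session
scene-reversal learning, for the scene-gated value-coding asymmetry of the
passive probe, and for above-chance retention after FSI removal fail: all
three presuppose weights that the closed loop cannot produce. They are
asserted as stated and left failing.

### 5.2 Divisive inhibition can express it, but the update rule cannot find it

Under the divisive reading the gains differ across scenes
($1/\mathit{FSI}^u_s$), so the drive difference becomes
$\sum_u (S^u_{OA} - S^u_{OB})/\mathit{FSI}^u_s$, which *is*
scene-dependent: the anti-symmetric configuration ($S^X$ favouring A, $S^Y$
favouring B) yields correct reversal behaviour. The learning dynamics,
however, never reach it. The update is proportional to the response itself
(growth multiplicative in the weights, with no decay or normalisation), and
the net reinforcement rate of a *globally* preferred object is positive in
*both* units whenever the small-reward penalty is weaker than the FSI gain
ratio ($|-0.5| < 0.6/1$). A transient object preference therefore
self-amplifies exponentially in both units and outruns the slower
anti-symmetric mode; simulations across policies (softmax β 0.3–5,
ε-greedy ε 0.1–0.3), sequencing modes and sessions up to 2000 trials find
the anti-symmetric solution in essentially no runs. The behavioural
signature is exactly "switching object choice, but not following the scene":
asymptotic scene-conditional accuracy ≈ 0.5.

### 5.3 What the model does reproduce

Three of the claimed contrasts are genuine properties of the implementation
and pass their acceptance checks:

* **Blockade null.** With flat FSI input, scene-conditional accuracy over
  the last 80 of 300 trials averages 0.50 (exact scene/object exchange
  symmetry; also verified as an equivariance property test).
* **No-scene control.** The fixed-value task is learned to >0.95 last-40
  accuracy under either FSI setting — value learning per se does not need
  FSIs, matching the blockade's task-selectivity.
* **Scene-weight ablation.** Deleting the learned scene weights (on top of
  FSI removal) collapses evaluation accuracy to 0.5 ± 0.03, the clean
  negative control of the retention mechanism.

A minor claimed invariant also fails in closed loop: each unit's *preferred
scene* is stable across training only under scene-balanced experience; the
runaway mode of Section 5.2 can drag the scene weights apart faster than the
0.4 FSI asymmetry and reverse the measured preference in most seeds.

### 5.4 What would rescue the claims

The analysis points at minimal modifications, all outside the published
model and therefore *not* defaulted here: a small-reward penalty stronger
than the FSI gain ratio; weight normalisation or decay to tame the
value-proportional growth; conjunctive object-×-scene synapses; or a firing
threshold calibrated so that FSI inhibition silences the non-preferred unit
from the start. Each can be explored with the exposed configuration fields
(`reward_signal_small`, `rectify`, `inhibition`, FSI magnitudes).

## 6. Electrophysiology pipeline

The unit-classification and response statistics follow the recording
methodology exactly:

* **Median waveform** — spike traces peak-aligned, pointwise median, cubic
  spline interpolation (default 10× upsampling) before measurement.
* **Peak–trough duration** — time from the global peak to the subsequent
  trough on the interpolated trace.
* **Baseline rate** — spikes in the 250 ms pre-scene windows divided by
  total window time; overlapping windows are an error, not silently merged.
* **Classification** — FSI iff duration < cutoff (800 µs, or 480 µs for the
  short-amplifier profile — a required input, never guessed from data) *and*
  rate > 2 Hz; MSN iff duration > cutoff *and* rate < 10 Hz. The published
  inequalities are strict on both sides, so boundary measurements are
  `unclassified` with a `boundary` flag rather than silently assigned.
* **Responsiveness** — two-sided paired t test on per-trial rates
  (counts normalised by the differing 350 ms/250 ms window lengths),
  significant at p < 0.05/n with Bonferroni correction; an exact sign-flip
  permutation test is available for small n.
* **Spike density** — sum of unit-mass Gaussians (σ = 15 ms) divided by the
  trial count, in Hz; the evaluation grid must resolve the kernel
  (spacing ≤ σ/3).

## 7. Numerical and reproducibility choices

* All randomness flows through one seed per entry point, expanded into
  deterministic per-stage child streams; the caller's RNG state is saved and
  restored. Identical (input, seed) pairs give byte-identical trial logs,
  and `run_to_dir()` manifests record MD5 checksums that reproduce exactly.
* Ties in `scene_preference()` break to the first-declared scene and are
  flagged; classification boundary hits are flagged (Section 6).
* Degenerate inputs are defined, not accidental: zero-trial sessions are
  valid; zero firing rates give empty spike trains; `LS = 0` makes updates
  exact no-ops; empty stimulus presentations respond 0.
* Problem sizes in the tests and acceptance script — e.g. 200 seeds × 300
  trials for the blockade null, 100 seeds × 160 trials for learning and
  probe statistics, 400-event synthetic units for classification — were
  chosen so that binomial/Poisson sampling error is well inside each
  criterion's tolerance while a full run stays in the low minutes on one
  core.

## 8. Known limitations

* The choice policy is invented; nothing in the model constrains β, and all
  behavioural results should be read conditional on the policy layer.
* No dopamine dynamics: reward enters only as the ±-valued teaching signal.
* No spiking or conductance-level neuron model; "responses" are unitless
  activations, so quantitative comparison to firing rates is out of scope.
* No forgetting term: retention across simulated days is trivially perfect
  and is therefore not presented as a prediction.
* The real-data analyses (population percentages, z and p values on monkey
  recordings) are out of scope; the ephys pipeline is validated on synthetic
  units only.
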