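---
title: "An adaptive temporal–causal network model of religion and empathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive temporal–causal network model of religion and empathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcnet)
```

## The modelling framework

`tcnet` simulates *temporal–causal networks*: directed labelled graphs whose
node activations evolve in continuous-valued, discrete-time dynamics. Three
labels fully determine the dynamics:

* a **connection weight** $\omega_{X,Y}$ per edge, normally in $[0,1]$,
  negative for inhibiting influences;
* a **combination function** $c_Y(\cdot)$ per state that aggregates the
  weighted incoming impacts $\omega_{X_i,Y}X_i(t)$ into a single target
  activation — here the advanced logistic sum
  $\mathrm{alogistic}_{\sigma,\tau}$, with steepness $\sigma$ and threshold
  $\tau$;
* a **speed factor** $\eta_Y$ per state scaling how fast the state moves
  toward its aggregated impact.

Each step applies the Euler update
$Y(t+\Delta t) = Y(t) + \eta_Y[\mathrm{aggimpact}_Y(t) - Y(t)]\Delta t$.
Because $\mathrm{alogistic} \in [0,1)$ and $\eta_Y\Delta t \le 1$ makes the
update a convex interpolation, activations can never leave $[0,1]$; this
boundedness is asserted property-style in the test suite.

Adaptive connections evolve by simultaneity-based Hebbian learning
("neurons that fire together, wire together") with extinction:
$\omega(t+\Delta t) = \omega(t) + [\eta_H X(t)Y(t)(1-\omega(t)) -
\zeta_H\,\omega(t)]\Delta t$. The factor $1-\omega$ bounds the weight by 1;
for constant activations the weight converges to
$\eta_H XY/(\eta_H XY + \zeta_H)$, which the tests verify against iterated
simulation.

### Numerical choices

* **Update scheme.** All aggregated impacts and all Hebbian increments are
  computed from the time-$t$ values before any state or weight advances
  (synchronous update). The difference equations are stated simultaneously,
  and a sequential scheme would make the result depend on an arbitrary
  state ordering; a dedicated test asserts that a freshly updated value
  cannot leak into the same step.
* **Zero exactness.** $\mathrm{alogistic}$ is evaluated in the direct
  two-term form so that an all-zero input yields exactly 0 (both logistic
  terms are then the same expression), and negative raw values are clipped
  to exactly 0.
* **Sub-unity cap.** Mathematically $\sup \mathrm{alogistic} = 1$ is never
  attained, but in double precision the expression rounds to 1.0 once
  $\sigma(\Sigma V - \tau) \gtrsim 37$. The implementation caps the result
  at the largest double below 1 so the strict bound survives rounding.
* **Time units.** Reported times are model-time units $t = k\,\Delta t$;
  with the canonical $\Delta t = 0.25$ and 500 steps a run spans
  $t \in [0, 125]$. All published landmark times fit inside this span,
  which is why they are read as model time rather than step indices.
* **Clamping.** World states without inbound connections are held at their
  initial value (they are pure stimuli, and the framework gives them no
  dynamics); the two world states that do receive feedback — the prayer
  sound and the expressed emotion — evolve like any other state.
* **Determinism.** The engine contains no randomness; the only stochastic
  component in the package is the fixture generator for the oracle tests,
  which is a pure function of its seed.

## The religion–empathy network

`build_religion_network()` constructs the canonical 54-state model. Per
valence (1 = empathic, 2 = dis-empathic): five world states (God's action,
God's emotion, the general God-image, a prayer being heard, the person's
own expressed emotion), five sensor states, five sensory representations
(the three God-image components plus the own-emotion and predicted-effect
representations), three preparation states (behaviour, emotion, prayer),
four ownership states (God/Self × action/emotion), three execution states
and a feeling state. Two states are shared across valences: the goal `gs`
of earning God's love (initially 1) and its fulfilment state `gfs`, which
inhibits the goal (weight $-0.4$ — the model's single inhibiting
connection, read as goal fulfilment damping the goal drive).

Mechanistically, the God-image is built from external input and from the
person's own prayer (both an external loop through the heard prayer and an
internal influence from the prayer preparation state); mirror-neuron links
connect the God-image representations to the person's preparation states;
the as-if body loop lets a prepared emotion generate its own sensory
representation and feeling without overt execution; and the ownership
states gate both preparation and execution. The four God-image connections
per valence (general image → action representation, general image → emotion
representation, and action ↔ emotion representations) adapt by Hebbian
learning with learning and extinction rates 0.5 and initial weight 0.5
(initial adaptive weights are not part of the published parameterisation;
0.5 is the neutral midpoint, and scenario-wide weight overrides also apply
to them).

The ownership-state nomenclature is inconsistent across the published
tables; the package uses four canonical ownership states per valence wired
per the prose description of the ownership model (Self-ownership of
behaviour from the God-action representation, the predicted effect, and the
feeling state; and so on). The goal state keeps its printed self-connection.

### Connection weights

Default weights are the *neutral person*: by edge role, sensing edges 0.8
(world → sensor → representation), internal edges 0.7, effector edges 0.55
(into and out of the execution states). Published scenario strengths are
given only as "around $x$"; the profiles freeze them to $x$ exactly:

| scenario | parameterisation |
|---|---|
| `neutral` | canonical defaults, valence-symmetric |
| `empathic` | all valence-1 weights 0.8, valence-2 weights 0.1 |
| `disempathic` | exact valence swap of `empathic` |
| `asd` | mirroring and as-if (mentalizing) edges 0.3; God-image edges 1.0 (v2) vs 0.8 (v1); stimuli 1.0 (v2) vs 0.5 (v1) |
| `atheist` | Self-ownership path 1.0, God-ownership path 0.3, religious-source couplings 0.3, goal state starts at 0.8 |
| `fundamentalist` | valence-2 weights 1.0 vs valence-1 0.1; God-ownership 0.8 (v1) / 0.3 (v2) as printed; Self-ownership 0.1; God-image→preparation and preparation→execution 1.0 |

The seemingly inverted God-ownership values in the fundamentalist profile
(stronger for the *empathic* valence) follow the published wording
verbatim. The scope of the ASD "dis-empathic connections around 1.0" is
ambiguous in the source; it is applied to the God-image sensing and
representation edges.

## Calibration of the combination-function parameters

Steepness and threshold values are not part of the published
parameterisation. The package assigns one $(\sigma, \tau)$ pair per state
role and froze them after a single calibration pass against the published
trajectory features (weights were never touched):

| role | $\sigma$ | $\tau$ | rationale |
|---|---|---|---|
| world (fed-back) | 5 | 0.3 | single moderate input |
| sensor | 8 | 0.55 | crisp transduction of a 0.8-weighted stimulus |
| God-image representation | 5 | 1.05 | several converging inputs; keeps the God-image silent under weak (atheist-level) drive |
| body/effect representation | 5 | 0.35 | single-input as-if loop must sustain itself |
| preparation | 3 | 0.95 | shallow slope so plateaus sit mid-range rather than saturating |
| ownership | 5 | 1.4 | requires converging representation evidence; paces execution onset |
| execution | 20 | 1.6 | near-switch behaviour: fires only on strong joint ownership + preparation drive |
| feeling | 5 | 0.3 | single-input chain |
| goal | 10 | 0.35 | self-sustaining until inhibited by fulfilment |
| goal fulfilment | 6 | 1.4 | needs a developed God-image |

The God-image and body representations deliberately use different
thresholds: a single shared pair cannot simultaneously keep the atheist's
God-image weak (it must not ignite from the internal prayer loop alone) and
let the atheist's as-if emotion loop reach the published ~0.9 emotion
preparation plateau.

Under this frozen calibration, with the shared settings ($\Delta t = 0.25$,
500 steps, $\eta = 0.17$ everywhere, $\eta_H = \zeta_H = 0.5$):

* empathic scenario: dis-empathic preparation peaks at 0.018 (published
  bound 0.3); empathic execution onset at $t = 32.8$ (behaviour) and 39.0
  (emotion) against the published ~40; equilibrium at $t = 60$ and 71
  against the published ~70, at activation 1.000 and 0.988 against the
  published 1.0;
* dis-empathic scenario: the exact mirror (asymmetry $\le 10^{-12}$);
* atheist scenario: emotion preparation plateaus at 0.905 against the
  published ~0.9, the feeling states at ~0.71, the goal state stays high
  (~0.96) because it is never fulfilled, and the God-image representations
  stay below 0.02;
* in every scenario the suppressed valence's execution states stay below
  $10^{-13}$, and all activations and adaptive weights remain in $[0,1]$.

### Known limitations

* With scenario-independent per-state thresholds, the delayed empathic
  execution onset (~40) forces an execution threshold of about 1.6 — more
  drive than the neutral, ASD and fundamentalist scenarios can ever deliver
  through their weaker effector/ownership weights (~1.2–1.4). In those
  three scenarios execution therefore stays near zero, whereas the
  published account describes them as executing. The within-scenario
  *relative* structure (valence symmetry in `neutral`, suppression of the
  empathic valence in `asd`/`fundamentalist`) is preserved.
* The published landmark values (0.3, 40, 70, 1.0, 0.9) are read off
  simulation figures, not defined operationally; the feature extractors
  fix onset threshold 0.05 and equilibrium tolerance 0.01 as defaults, and
  "never executed" is operationalised as a peak at most 0.05.
* The engine is deliberately minimal: synchronous Euler only (no
  continuous-time solver), one combination function, no stochastic
  dynamics, a single Self with a single God-image.

## What the tests do and do not show

The unit and property tests cover the engine against an independently coded
per-connection reference implementation (100 random 3–8-state networks,
agreement to $10^{-12}$), the analytic properties of the combination
function ($10^4$ random parameter draws), Hebbian boundedness and fixed
points, the golden hand-transcribed edge list of the canonical model, exact
mirror symmetry, and the calibrated trajectory features listed above. They
exercise the model's internal consistency and its agreement with the
published trajectory descriptions; they say nothing about empirical human
behaviour — the model was never fitted to human data, and neither is this
implementation. Default test problem sizes (50-step oracle runs, 500-step
scenario runs) keep the full suite under two minutes on one CPU.
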