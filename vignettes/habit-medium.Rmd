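---
title: "A deformable sensorimotor medium: model, numerics and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deformable sensorimotor medium: model, numerics and experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idsm)
```

## The model

This package simulates habits — self-maintaining patterns of sensorimotor
behavior — with a plastic controller we call a deformable sensorimotor
medium.  The medium is a growing collection of *nodes*.  Each node
$N = \langle \mathbf p, \mathbf v, w \rangle$ records one moment of the
agent's history: the sensorimotor state $\mathbf p$ it was created at, the
sensorimotor velocity $\mathbf v$ it observed there, and a scalar weight
$w$ that tracks how strongly that memory has since been reinforced.  All
node bookkeeping happens in *normalized* sensorimotor space: every sensor
and motor range is mapped linearly onto $[0,1]$, so one point of the space
is one complete sensor-plus-motor state of the agent.

Two kernels determine a node's influence at the current state $\mathbf x$:

* a distance kernel
  $d(\mathbf p, \mathbf x) = 2 / (1 + e^{k_d \lVert \mathbf p - \mathbf x \rVert^2})$
  with $k_d = 1000$, equal to 1 at the node and already $\sim 10^{-4}$ at
  distance $0.1$ — node influence is strictly local;
* a weight kernel $\omega(w) = 2 / (1 + e^{-k_\omega w})$ with
  $k_\omega = 0.0025$, a very flat sigmoid: a node is "neutral"
  ($\omega = 1$) at $w = 0$ and must gain or lose weight on the order of
  $10^3$ before its influence saturates at 2 or fades toward 0.

The local node density is
$\varphi(\mathbf x) = \sum_N \omega(N_w)\, d(N_\mathbf{p}, \mathbf x)$.
A new node (with $w = 0$, at the current state, carrying the current
velocity estimate) is added only while $\varphi(\mathbf x) < k_t = 1$, so
the medium does not record any region more densely than the threshold.
Weights evolve as $\dot w = -1 + 10\, d(N_\mathbf{p}, \mathbf x)$: a
steady decay, opposed by reinforcement whenever the agent revisits the
node's neighborhood.  Nodes are never deleted; they fade through
$\omega$.

The medium drives the motors through a kernel-weighted *average* over the
activated nodes (those older than 10 time-units — newly minted nodes must
not drown out the history they are meant to extend):

$$
\frac{d\boldsymbol\mu}{dt}
 = \frac{1}{\varphi(\mathbf x)} \sum_N \omega(N_w)\, d(N_\mathbf{p},\mathbf x)
   \left( N_\mathbf{v} + \Gamma(N_\mathbf{p} - \mathbf x, N_\mathbf{v}) \right)^{\!\boldsymbol\mu}
$$

The *velocity factor* $N_\mathbf{v}$ replays the recorded flow; the
*attraction factor* pulls the state toward the node, with
$\Gamma(\mathbf a, \mathbf v) = \mathbf a - \frac{\mathbf a \cdot \mathbf v}{\lVert \mathbf v \rVert^2}\mathbf v$
removing the component parallel to the node's velocity so attraction
cannot fight the replay.  The superscript $\boldsymbol\mu$ keeps only the
motor components: the medium can only act through the motors, sensors are
determined by the world.

Together these rules make trajectories self-reinforcing: enacting a
pattern recreates the conditions (reinforced, re-created nodes) for
enacting it again — a habit, in the same sense in which a trail through
grass is maintained by being walked.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `k_d` | 1000 | per squared normalized distance | locality of node influence |
| `k_omega` | 0.0025 | per weight unit | flatness of weight influence |
| `k_t` | 1 | density | node-creation threshold |
| `activation_delay` | 10 | time-units | delay before a node drives motors |
| `decay_rate` | 1 | weight/time-unit | dissipation of unvisited nodes |
| `reinforcement_gain` | 10 | weight/time-unit | reinforcement at zero distance |
| `dt` | 0.01 | time-units | Euler step for all dynamics |
| `phi_floor` | 1e-300 | density | guard for the field normalization |

## Numerical choices

**Integration.**  All continuous dynamics (weights, motor updates, body
kinematics, trainer smoothing) use explicit fixed-step Euler at
`dt = 0.01` time-units.  At this step the re-enacted behaviors are
insensitive to halving `dt`, and the one-step backward difference of the
normalized trajectory doubles as the velocity estimate recorded in new
nodes.  Across a relocation event the backward difference would be the
"velocity" of a teleport, so the runner resets the difference to zero for
that one step.

**The normalization guard.**  The field above is an average, so it is
well defined wherever any kernel value is positive; with `k_d = 1000`
those values are astronomically small far from the node cloud
(e.g. $\sim 10^{-40}$ at distance 0.3) yet the average remains meaningful
and is exactly what lets a released agent far from its trained orbit find
its way back.  `phi_floor` therefore defaults to just above
double-precision underflow: the motors hold only when every kernel has
underflowed to zero.  A larger floor would freeze the agent in any
unfamiliar region.

**Which nodes count where.**  The creation threshold compares the density
over *all* nodes — otherwise the medium would lay unbounded trails of
not-yet-activated nodes in its first ten time-units.  The field and its
normalization use the *activated* nodes only, since only those influence
the motors.

**Degenerate stored velocities.**  When a node's recorded velocity is
numerically zero (possible after a relocation or a zero-range seeding
walk), the projection in $\Gamma$ is undefined; the attraction vector is
then used unprojected.

**Step order.**  Within one step the medium evaluates the field, then
updates weights, then checks node creation, then advances its clock — a
node can never reinforce itself or steer the agent at the instant of its
own creation.

**Trainers.**  The circular and oscillatory trainers set the motors
directly from their closed forms; the Braitenberg-style controllers pass
their clipped targets through the smooth update $\dot m = \chi - m$.
Experiment presets start the body in the state the trainer prescribes at
$t = 0$; setting motors discontinuously at the first step would record a
node whose velocity is the jump divided by `dt`, a spurious memory three
orders of magnitude faster than anything the agent can do, which later
destabilizes re-enactment.

**Lattice and recurrence conventions.**  The region coding uses
half-open bins with the top bin closed (a normalized value of 1.0 falls
in bin 9 of 10).  The recurrence fraction uses a symmetric temporal guard
(nearest in-window state at least `guard` time-units away in either
direction), the usual recurrence-plot convention, so an exactly repeating
loop scores 1.

## The bodies

The one-dimensional robot moves on an unbounded line with a light at the
origin; its motor *is* its velocity ($\dot x = m$, $m \in [-1,1]$) and
its sensor reads $s = 1/(1+x^2)$.  Its sensorimotor space is 2-D.

The two-wheeled robot lives in a $4 \times 4$ arena with periodic
boundaries and a light at the center.  Kinematics:
$\dot x = \cos\alpha\,(m_l+m_r)$, $\dot y = \sin\alpha\,(m_l+m_r)$,
$\dot\alpha = 2(m_r-m_l)$.  Two directional sensors sit on the rim of the
radius-0.25 body at $\pm\pi/3$ from the heading and read
$s = (\hat{\mathbf b} \cdot \hat{\mathbf c} + 1) / (1 + D^2)$, where
$\hat{\mathbf b}$ is the facing direction, $\hat{\mathbf c}$ the unit
vector toward the light and $D$ the minimal-image distance: a directional
signal with inverse-square-like falloff, in $[0, 2]$.  Distances in the
periodic arena always use the minimal-image convention.  Its
sensorimotor space is 4-D: $(m_l, m_r, s_l, s_r)$.

Normalization ranges are fixed per body (motors $[-1,1]$; 1-D sensor
$[0,1]$; 2-D sensors $[0,2]$).  Neither body has inertia, friction,
sensor noise or a mobile light.

## The experiments

```{r presets, eval = FALSE}
run <- run_experiment(preset_motor_circle(seed = 1))
run <- run_experiment(preset_oscillation_1d(seed = 1))
run <- run_experiment(preset_trained_2d("photophobia", seed = 1))
run <- run_experiment(preset_random_init_2d(seed = 1))
```

* **Motor-circle imprinting** — the 2-motor, 0-sensor agent is driven on
  the circle $m_1 = 0.75\cos(2\pi t/10)$, $m_2 = 0.75\sin(2\pi t/10)$ for
  20 time-units, released, and has its motors randomized at $t = 30$; the
  medium then steers the motors back onto the trained cycle.  Over the
  final 20 time-units of a 100-time-unit run the re-enacted orbit has
  radius within a few percent of 0.75 and period within a few percent
  of 10.
* **1-D oscillation** — trained with $m = \cos(t/2)/2$ from $x = -2.5$
  for 20 time-units, the robot continues oscillating at the trained
  amplitude and distance from the light, and resumes doing so after being
  relocated back to $x = -2.5$ at $t = 35$.
* **Functional habits** — the wheeled robot is trained for 100 time-units
  by one of three Braitenberg-style controllers (simple phototaxis,
  sinusoidal phototaxis, photophobia), with a relocation to a random pose
  and random motors every 50 time-units throughout the run.  After
  training, the enacted habit keeps phototaxis-trained robots closer to
  the light than photophobia-trained ones (the mean minimal-image
  distance over the post-training window orders accordingly).  We run the
  free phase for 400 time-units — one evaluation window — which is enough
  to demonstrate the ordering while keeping a full three-behavior
  comparison inside a few minutes of compute.
* **Emergence** — no training at all: the medium is seeded with 5000
  nodes from 100 random walks of 50 steps (uniform step components in
  $[-0.05, 0.05]$, reflected at the boundary of the unit volume, weight
  0, all active from the start), and the robot runs ten 100-time-unit
  trials from random poses, the medium persisting across trials.  In a
  typical run most trials settle into repetitive behavior: recurrence
  fractions above 0.8 in the final 25 time-units with no new lattice
  regions visited.

A note on what the seeding walk lengths mean: only the two totals
(5000 nodes, 100 walks) are inherent to the protocol; 50 steps per walk
is the implied quotient.  "Inverted" boundary handling is read as
negating the offending step component; reflecting the resulting position
instead would differ only at second order in the step size.

## What the medium can and cannot re-enact

The medium maps sensorimotor states to motor change, so it can only
re-enact behavior that is a function of the sensorimotor state.  A
training signal that switches on time alone (the same state followed by
different continuations) cannot be encoded: the two continuations average
at the shared states.  Node weights on an enacted cycle are *not*
typically net-increasing: with the default constants, reinforcement
accumulated while the state sweeps past a node (roughly
$10 \int d\,ds / v$ per lap) is smaller than the decay paid over a lap
for any cycle longer than $\sim 0.7$ in normalized arc length.  Habit
persistence over the timescales simulated here rests on the flatness of
$\omega$ — reinforced nodes fade far more slowly than their influence
matters — and on fresh node creation along the enacted path, not on
weight growth.  Over much longer horizons all unvisited structure
dissipates, which is the dissipative, far-from-equilibrium character the
model is meant to exhibit.

## What the synthetic experiments do and do not show

Everything in this package is generated by the simulation itself; there
is no external data.  Passing experiments therefore show that the
medium's dynamics produce imprinting, functional training and spontaneous
habit formation *under these idealized bodies and environments* —
noise-free sensors, inertia-free kinematics, a static light.  They do not
show robustness to sensor noise, to body damage, to non-stationary
environments, or that the particular kernel constants are special; the
parameters are exposed precisely so such questions can be explored.

## Known limitations

* Runtime grows linearly with node count per step; media beyond a few
  tens of thousands of nodes become slow in this implementation.
* Trial categorization into named habit classes is left to the user; the
  package emits region sequences, recurrence fractions and PCA
  projections as raw material.
* Only the motor components of stored node velocities are ever used by
  the field; sensor components are stored for forward compatibility with
  richer reinforcement rules.
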