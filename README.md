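# idsm

Habits — looking left before crossing, pacing a familiar route — can be
modeled as *self-maintaining patterns of sensorimotor behavior*: patterns
that, by being enacted, reinforce the very mechanism that generates them.
This package implements such a model for researchers in embodied
cognition, behavioral dynamics and minimal-cognition robotics: a plastic,
node-based controller (a *deformable sensorimotor medium*) coupled to
simulated robot bodies, together with the training protocols and analyses
needed to imprint, probe and discover habits.

## The model in brief

The agent's sensor and motor ranges are rescaled onto the unit cube; one
point **x** of this normalized sensorimotor (SM) space is one complete
sensor+motor state.  As the agent behaves, the medium accumulates *nodes*
N = ⟨**p**, **v**, w⟩ — the SM position visited, the SM velocity observed
there, and a weight.  Nodes are created while the local density

φ(**x**) = Σ_N ω(N_w) · d(N_**p**, **x**),  with
ω(w) = 2/(1+e^(−k_ω w)) and d(**p**, **x**) = 2/(1+e^(k_d‖**p**−**x**‖²)),

is below a threshold (k_t = 1); weights obey ẇ = −1 + 10·d(N_**p**, **x**),
decaying steadily and being reinforced on revisits.  Activated nodes
(older than 10 time-units) drive the motors through the density-normalized
field

dμ/dt = φ(**x**)⁻¹ Σ_N ω(N_w) · d(N_**p**, **x**) · (N_**v** + Γ(N_**p**−**x**, N_**v**))^μ,

where Γ removes from the attraction the component parallel to the node's
velocity.  Repeated trajectories reinforce and re-create the nodes that
generate them: habits form, persist while enacted, and dissipate when
prevented.

Bodies provided: a 1-D robot (motor = velocity, sensor s = 1/(1+x²)) and
a two-wheel robot with two directional light sensors in a periodic 4×4
arena; trainers: a motor-space circle, a 1-D oscillation, and three
Braitenberg-style controllers (simple/sinusoidal phototaxis, photophobia).

## Worked example

Train the 2-motor agent on a circle of radius 0.75 and period 10 for
20 time-units, randomize its motors at t = 30, and let the medium steer:

```r
library(idsm)
run <- run_experiment(preset_motor_circle(seed = 1))
tr  <- run$trajectory

late <- tr$t >= 80 & tr$t <= 100
mean(sqrt(tr$m1[late]^2 + tr$m2[late]^2))
#> [1] 0.7545626
oscillation_stats(tr$t, tr$m1, window = c(60, 100))$period
#> [1] 10.2538
run$idsm
#> <idsm> 2-dimensional (2 motor), 108 nodes, t = 100
```

The released trajectory converges back to a closed orbit whose radius
(0.755 motor units) and period (10.25 time-units) match the training
signal to within a few percent: the behavior was imprinted, perturbed,
and re-enacted from memory.

Other entry points: `preset_oscillation_1d()` (trained oscillation,
relocation, resumption), `preset_trained_2d(kind)` (functional
phototaxis/photophobia habits; compare
`mean_distance_to_light()` across kinds), `preset_random_init_2d()`
(habit emergence from a 5000-node random-walk seeding;
`recurrence_fraction()` and `region_id_sequence()` quantify settling),
`flow_field()` (frozen-medium flow portraits), and
`write_nodes()`/`read_nodes()` for bit-exact medium snapshots.  A thin
CLI lives at `inst/cli/idsm.R`.  The methods vignette
(`vignettes/habit-medium.Rmd`) documents the model, parameters and
numerical choices.

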