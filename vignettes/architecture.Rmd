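---
title: "A layered embodied architecture for goal-directed choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layered embodied architecture for goal-directed choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dacsim)
```

## The model

`dacsim` simulates a point agent in a continuous 2D arena under a
Distributed Adaptive Control (DAC)-style architecture: three control layers
stacked over a somatic level, each able to claim the motor plant, with the
higher layers engaging only when the lower ones are quiescent.

**Somatic level.** The body: a pose $(x, y, \theta)$, distal exosensing,
interoception and actuation. The percept is a fixed-length vector — for each
of $n$ equally spaced body-frame rays, the distance-attenuated feature
vector of the nearest landmark assigned to that ray (landmarks are split
bilinearly across the two adjacent rays, so the percept varies continuously
with pose), plus one binary channel per contextual cue. Essential variables
(e.g. energy) decay each step, are replenished by consuming outcomes, and
define drives $d = \max(0, \text{set point} - \text{level})$. Motor noise is
additive Gaussian with a single standard deviation shared by the egocentric
components and the allocentric vector components, so comparisons between
action encodings share one noise budget. Interior walls stop motion at the
wall face; the outer boundary acts as a guard rail (motion slides along it).

**Reactive layer (RL).** A set of homeostatic behaviour systems. Each one
senses an affordance gradient — a spatial field built from isotropic
Gaussian source kernels, $F(p) = \sum_s A_s e^{-\|p - c_s\|^2 / 2\sigma_s^2}$
— and regulates its self-essential function, the discrepancy
$\mathrm{sef} = \text{desired} - \text{sensed}$. Action proposals perform
gradient ascent (or descent, when the sensed value exceeds the desired one)
by finite-difference probing at `rl.n_probe` headings; field values below
the detection floor `world.sense_floor` read as zero at the agent *and* at
the probes, so out-of-range gradients cannot be climbed. An allostatic
controller sets priorities by moving each desired value with the drive of
the need served: $\text{desired} = \text{baseline} + \kappa d$, clipped to
the field's attainable maximum. A strict winner-take-all over proposal
strengths ($\text{gain} \cdot |\mathrm{sef}|$, ties by priority rank) emits
exactly one reactive action per step.

**Adaptive layer (AL).** A resource-allocating prototype quantizer learns
perceptual states: percepts farther than the vigilance radius `al.init_tol`
from every stored prototype recruit a slot (recycling the least-recently
used one when the bank is full, which keeps prototypes in active service
stable across context switches); matched prototypes move toward the percept
by the delta rule with rate `al.alpha`. The winning prototype's distance is
the reconstruction error $\varepsilon$, smoothed into a running average
$\bar\varepsilon$ with rate `al.lambda`. Each prototype carries a scalar
valence $u$ updated by the single-stimulus Rescorla-Wagner rule
$u \leftarrow u + \eta(\mathrm{US} - u)$ at reinforcement and
$u \leftarrow u + \eta(0 - u)$ when the conditioned stimulus occurs without
reinforcement — including any step on which a conditioned response is
emitted unreinforced, so CRs that chase non-predictive stimuli extinguish.
When $|u|$ reaches `al.theta_cr` the layer emits a conditioned response:
a turn toward (appetitive) or away from (aversive) the stimulus bearing,
read from the dominant ray block of the active prototype itself. The CR
replaces the reactive action when its strength exceeds the reactive
strength, and otherwise adds a proportional turn bias.

**Contextual layer (CL).** When both lower layers bid below
`cl.theta_gate`, the CL engages. Well-predicted steps
($\varepsilon < \bar\varepsilon$, the acquisition threshold) are stored in a
short-term memory ring as *segments* — the perceptual state, the executed
action (with its egocentric projection) and the pose. When an outcome is
reached, an agency check (the site was armed by the agent's own action, and
a segment was acquired within the last `cl.W` steps) gates consolidation:
the STM content becomes one long-term-memory sequence conserving order,
tagged with a goal descriptor and a valence marker, with per-segment goal
distances $d_i$ counting events to the goal; STM is then reset.
Free, experimenter-scheduled deliveries are never consolidated.

Action selection is the four-factor rule. Each segment carries

$$w_i = e_i \,(c_i + c_0)\, \frac{\max(0, v)}{1 + d_i}, \qquad
  e_i = e^{-\|x - p_i\|^2 / 2\sigma_e^2},$$

where $e_i$ is perceptual evidence for the stored state $p_i$, $c_i$ the
working-memory trigger (chaining), $1/(1+d_i)$ goal fidelity, and
$v = \text{valence}_{\text{now}} \times (1 + \text{drive})$ the goal value
re-read from the outcome table at decision time. Sequences whose current
value is negative contribute repulsive weights of the same magnitude;
a value of exactly zero silences the whole sequence, which is what makes
the layer devaluation-sensitive without re-learning. Segments are
*activated* by evidence or priming — at least `cl.tau_act` of the best
current match, or a trigger above `cl.c_act` — and the four-factor weights
arbitrate among the activated ones (contributors are those within
`cl.tau_c` of the maximum). Evidence below `cl.e_min` contributes nothing,
so the layer abstains honestly when nothing in memory matches (e.g. right
after a kidnapping) instead of acting on garbage. The executed action is a
weighted sum over contributors: in allocentric mode, displacement vectors
toward each contributor's next waypoint (pure-pursuit: the first stored
pose of its sequence beyond `cl.lookahead`, walked from the closest
remaining pose so a lagging match can never target a point behind the
agent), scaled to `world.v_max`; in egocentric mode, the score-weighted
circular mean of the stored body-frame turns and speeds. Contributors of
successive decisions become associated (chaining links, rate `cl.rho_C`)
and prime their successors' triggers with gain `cl.gamma` under decay
`cl.phi`. After an allocentric step the body re-orients along the commanded
velocity, so stored egocentric projections of waypoint runs remain
replay-consistent.

Exactly one layer's action is executed per step, and the CL acts only when
the gate was open — the step log records which.

## Parameters

All parameters live in one nested configuration (`dac_default_config()`,
YAML-overridable via `load_config()`); units are arena units and steps.
The ones that matter most:

| key | default | meaning |
|---|---|---|
| `world.v_max` | 0.5 | speed ceiling per step |
| `world.noise_sd` | 0.1 | motor noise sd (both encodings) |
| `world.sense_floor` | 1e-3 | affordance detection floor |
| `rl.kappa` | 0.5 | drive-to-desired coupling (allostasis) |
| `rl.gain` | 0.15 | SEF gain; keeps reactive bids below the gate |
| `al.K`, `al.init_tol` | 64, 0.4 | prototype slots and vigilance radius |
| `al.alpha`, `al.eta` | 0.1, 0.1 | prototype and valence learning rates |
| `al.theta_cr` | 0.1 | conditioned-response threshold |
| `cl.theta_gate` | 0.2 | sub-threshold gate for CL engagement |
| `cl.sigma_e` | 0.6 | evidence bandwidth |
| `cl.e_min` | 0.15 | evidence floor (abstention) |
| `cl.tau_act`, `cl.c_act` | 0.9, 0.5 | activation by evidence / priming |
| `cl.tau_c` | 0.5 | contributor threshold within the active set |
| `cl.lookahead` | 1.0 | pure-pursuit waypoint radius |
| `cl.L`, `cl.W` | 30, 10 | STM capacity and agency window |
| `cl.phi`, `cl.gamma`, `cl.rho_C`, `cl.c0` | 0.2, 0.9, 0.1, 0.2 | working-memory dynamics |

The evidence bandwidth was set from measured percept-distance scales of the
ray sensor: one motion step changes the percept by about 0.25, one
ray-sector reassignment by about 0.9, distinct arena regions by 1.4 or
more. At $\sigma_e = 0.6$ successive route states match strongly
($e \approx 0.92$), small heading errors still match usefully
($e \approx 0.35$), and distinct regions are far below the floor. The
vigilance radius 0.4 tiles route states finely enough that reinforced
prototypes stay local (no value leakage between a goal and the corridor
leading to it).

## What the protocols emulate

The synthetic arenas (`generate_arena_fixture()`) are deliberately minimal
analogues of standard paradigms, deterministic per `(kind, seed)`:

- **`lever_box`** — a conditioning chamber: entering the lever radius is a
  press; a food-odour field centred on the lever gives the reactive layer a
  taxon route; a box-wide cue encodes the training context.
  `run_devaluation()` trains, probes a baseline press rate under
  deprivation, devalues (outcome-table edit to $-1$ plus pairing with the
  negative US in a separate context arena — a distinct landmark and cue
  channel, no lever, no odour), then tests in extinction. The intact
  agent's contextual layer re-reads the devalued outcome and suppresses
  (indeed repels from) the lever; the lesioned (`disable_cl`) agent keeps
  pressing at its reactive, odour-driven rate. Both probe phases are run
  under deprivation so the drive state is comparable.
- **`foraging`** — home position, two odour-marked food sites, a ring of
  distinct landmarks making percepts position-specific everywhere.
  `run_foraging_kidnap()` teleports the trained agent mid-trial to a
  random previously visited location (identical locations for both
  variants, drawn from a dedicated stream) and logs recovery within a
  budget deliberately too short for random search.
- **`corridor_maze`** — an 18 x 6 corridor with wall cues, a goal beacon
  and pocket alcoves holding distracter landmarks (features within the
  evidence bandwidth of the goal's) and distracter odour sources: local
  maxima of the goal field that trap pure gradient ascent.
  `run_maze_distracters()` compares intact and lesioned agents;
  `run_entropy_benchmark()` uses the same maze as a route-learning
  benchmark: backward-shaped training (starts receding from the goal along
  the lower corridor lane, clear of the pocket basins), a familiarization
  pass and a final noise-free trial from the test start, then replay of
  the final consolidated route (`ltm_keep_recent()`) under a grid of motor
  noise levels in both action encodings. Trajectory dispersion at
  normalized-progress checkpoints (`compute_dispersion()`) is the
  behavioural-entropy proxy.
- **`open_field`** — a single appetitive field, used for the homeostatic
  and allostatic properties.

`run_conditioning()` needs no arena: a stationary agent receives paired
CS-US trials then CS-alone trials, and the logged value follows the
closed form $u_N = \mathrm{US}\,(1 - (1-\eta)^N)$ exactly, because a fixed
CS maps to one prototype.

What these fixtures do *not* emulate: occlusion and perspective (walls do
not block vision), sensor noise, continuous time, manipulator kinematics
(a press is a proximity event), or multi-outcome motivation. Passing tests
therefore show that the architecture produces the right *behavioural
signatures* under idealized sensing, not that it would do so on a physical
robot.

## Numerical and design choices

- **Determinism.** Every source of randomness draws from named streams
  derived from one master seed (`rng_registry()`), so an ablated variant
  consumes identical world noise until its behaviour actually diverges, and
  every protocol is byte-reproducible.
- **Ties.** Winner-take-all ties break by priority rank then list order;
  probe ties break to the lowest heading index; nearest-prototype ties to
  the lowest slot index. All tie rules are total, so trajectories are
  reproducible bit-for-bit.
- **Degenerate inputs.** An empty affordance field reads zero everywhere
  (and caps the desired value at zero, silencing the behaviour system); an
  empty LTM or an all-zero weight vector makes the contextual layer
  abstain; a prototype bank is seeded by the first percept.
- **Waypoint following.** The literal "move toward the next segment's
  pose" rule ping-pongs when stored poses are closer together than one
  step; the pure-pursuit lookahead (walked from the closest remaining
  pose) is the standard cure and leaves the documented examples unchanged.
- **Matching space.** Segments store and match the encoded percept state
  rather than the prototype centroid: quantized centroids made evidence
  discontinuous between consecutive segments, deadlocking sequence
  hand-off. Prototypes still mediate perception, STM gating, valence and
  the CR.
- **Kidnapping resets STM** (the displacement breaks the causal episode),
  so a post-kidnap goal cannot consolidate a teleport as if it were
  behaviour.

## Known limitations

- Body-frame (egocentric) replay of a learned route is fragile *even
  without motor noise*: it has no entry-heading anchor, so a small initial
  heading mismatch rotates the whole replayed trajectory. In the maze
  benchmark egocentric replay succeeds only sporadically at zero noise,
  while allocentric replay is deterministic and reliable. We report this
  as a property, not a defect: the contrast between the two encodings —
  allocentric success at every noise level, egocentric collapse, and
  dispersion growing with noise for both — is the phenomenon the benchmark
  exists to measure.
- The reactive layer alone cannot pass a distracter odour basin (it is a
  local maximum of its own objective); that is the intended failure mode
  of taxon control, and it is why training uses backward shaping.
- Valence is a scalar per prototype: outcome identity is carried by the
  contextual layer's goal descriptors, not by the adaptive layer.
- The problem sizes used throughout (20 seeds for the devaluation, kidnap
  and entropy protocols; 5 for the maze; trial budgets of 80-800 steps)
  are the package's defaults and keep the full test battery to a few
  minutes on one core.
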