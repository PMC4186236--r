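# dacsim

A seeded, testable simulator of a layered embodied cognitive architecture
in the Distributed Adaptive Control (DAC) tradition, for researchers who
study goal-directed versus habitual control, classical conditioning, and
navigation strategy (taxon versus route) in embodied agents.

A point agent lives in a continuous 2D arena and is controlled by three
coupled layers over a somatic level:

- a **reactive layer** of homeostatic behaviour systems, each performing
  gradient ascent on an affordance field F(p) = Σₛ Aₛ exp(−‖p−cₛ‖²/2σₛ²)
  to bring the sensed value to a desired value set allostatically from the
  body's drives, with strict winner-take-all arbitration;
- an **adaptive layer** that learns perceptual prototypes (vigilance-based
  resource-allocating quantization) and per-prototype valence by the
  single-stimulus Rescorla–Wagner rule u ← u + η(US − u), emitting
  conditioned responses that shape the reactive action;
- a **contextual layer** that stores well-predicted sensorimotor segments
  in short-term memory, consolidates them — gated by an agency check — into
  goal-labelled long-term sequences, and selects actions by a four-factor
  rule: perceptual evidence × chaining × goal fidelity 1/(1+d) × the goal's
  *current* value (re-read from the outcome table, so devaluing an outcome
  suppresses goal-directed action without re-learning).

Protocol runners reproduce the classic behavioural signatures at desk
scale: acquisition/extinction curves, outcome-devaluation dissociation
(goal-directed vs habitual), recovery from kidnapping during foraging,
maze navigation with distracters, and the robustness advantage of
allocentric over egocentric action encoding under motor noise
("behavioural entropy").

## Worked example

```r
library(dacsim)

rc <- run_conditioning(n_acq = 50, n_ext = 50)
cat("value after 50 paired trials:   ", rc$u_acq, "\n")
cat("value after 50 CS-alone trials: ", rc$u_final, "\n")

dv <- run_devaluation(n_seeds = 4)
print(dv$metrics[, c("seed", "variant", "base_rate", "test_rate", "drop")])
```

prints

```
value after 50 paired trials:    0.9948462
value after 50 CS-alone trials:  0.005127214
  seed   variant  base_rate  test_rate drop
1    1    intact 0.09666667 0.00000000    1
2    1 lesion_cl 0.09333333 0.09333333    0
3    2    intact 0.09666667 0.00000000    1
4    2 lesion_cl 0.09333333 0.09333333    0
5    3    intact 0.09666667 0.00000000    1
6    3 lesion_cl 0.09333333 0.09333333    0
7    4    intact 0.09666667 0.00000000    1
8    4 lesion_cl 0.09333333 0.09333333    0
```

The conditioning value after 50 paired trials equals the delta-rule closed
form 1 − 0.9⁵⁰ = 0.9948462 exactly, and extinguishes geometrically. In the
devaluation table, `base_rate` and `test_rate` are lever presses per step
before and after the reward is devalued: the intact agent suppresses
pressing completely (`drop` = 1) because its contextual layer re-reads the
now-negative outcome value, while the contextual-layer-lesioned agent
(`lesion_cl`) keeps pressing at its habitual, odour-driven rate
(`drop` = 0) — the classic goal-directed/habitual dissociation.

Other entry points: `run_foraging_kidnap()`, `run_entropy_benchmark()`,
`run_maze_distracters()`, the arena generator `generate_arena_fixture()`,
and the simulation core `dac_sim()` / `dac_step()` / `run_phase()`. A thin
command-line front end is installed at `inst/cli/dacsim`
(`dacsim run ...`, `dacsim bench devaluation|entropy|foraging|maze ...`).
The methods vignette (`vignettes/architecture.Rmd`) documents the model,
every parameter, and the design decisions.

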