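# tpsreg

Intensity-based rigid+scale registration of 2D grayscale images (typical
use: aligning single slices of multimodal brain MRI), driven by a
membrane-computing optimizer: a three-level **tissue P system** whose
compartments evolve candidate transforms with particle-swarm
velocity–position rules and exchange their local optima over bidirectional
membrane channels.

The package is for researchers studying metaheuristic optimizers for image
registration: it provides the membrane optimizer, the standard comparison
optimizers (real-coded GA, global-best PSO, PSO with Powell-style
refinement), a synthetic brain-phantom generator with T1/T2-like contrast
pairs, and a seeded benchmark harness — so the full experimental protocol
runs from code alone, with no external image downloads.

## The model

**Objective.** Registration maximizes the mutual information between the
reference image A and the floating image B resampled under a candidate
transform:

    MI(A, B) = Σ_{a,b} p(a,b) · log2[ p(a,b) / (p(a) p(b)) ]

with `p(a,b)` estimated from a joint histogram of intensities quantized
into 64 equal-width bins on [0, 1], computed over the jointly valid region
only (pixels exposed by the transform are masked out, never counted as
background agreement). MI is reported in bits; the log base rescales the
objective without moving its argmax.

**Transform.** A candidate solution is `(x, y, θ, Z)`: translation `x`
pixels **up** and `y` pixels **left** (note: vertical-first, positive
toward row/column 0 — this differs from the usual image convention and is
used consistently throughout), rotation `θ` degrees counterclockwise, and
isotropic scale `Z` about the image center. The fixed composition order is
scale → rotate → translate; resampling is inverse-mapping bilinear
interpolation, exact (pure index permutation) for quarter-turn rotations
with integer shifts.

**Optimizer.** 13 membranes in a fixed tree: one output membrane, three
level-2 aggregators, nine level-3 membranes holding 10 particles each
(a 90-particle system). Per step, each level-3 membrane updates its
particles with a three-attractor swarm rule — inertia plus pulls toward the
membrane's local best, a randomly chosen sibling's best, and the parent's
best — then siblings exchange local bests, parents collect child bests and
substitute their own by max-selection, and the output membrane records the
global best. All selections keep the incumbent on ties, so every best-score
trace is non-decreasing. The run halts after a fixed number of steps
(default 40) and is a pure function of (images, config, seed).

## Worked example

```r
library(tpsreg)

# reference: synthetic brain slice; float: the same slice moved 8 px up,
# 6 px left, rotated 5 degrees CCW (the classic single-modal construction)
ph  <- make_phantom(phantom_spec(size = 128, seed = 1))
flt <- make_float(ph$image, transform_params(8, 6, 5, 1))
attr(flt, "true_inverse")
#> <transform: x=-8.4925 px (up)  y=-5.2799 px (left)  theta=-5.0000 deg  Z=1.0000>

similarity(ph$image, flt, transform_params())   # MI before registration
#> [1] 0.6704808

cfg <- evolution_config(bounds = rbind(x = c(-15, 15), y = c(-15, 15),
                                       theta = c(-15, 15), Z = c(1, 1)),
                        seed = 42)
run_tps(ph$image, flt, cfg)
#> <registration_result [tpsysir]: MI = 2.3467 bits after 40 steps (3690 evals, seed 42)>
#> <transform: x=-8.5004 px (up)  y=-5.2826 px (left)  theta=-5.0318 deg  Z=1.0000>
```

The recovered transform matches the ground-truth inverse to ~0.01 px and
~0.03°, and MI rises from 0.67 bits (unregistered) to 2.35 bits (the
reference's own entropy ceiling at this bin count). Note the ground truth
is the *inverse* of the construction parameters under the documented
composition order — `invert_params()` computes it, and `make_float()`
attaches it.

`run_experiment()` repeats such registrations over seeded repetitions for
several optimizers and summarizes per-parameter absolute deviations and MI
as Max / Min / Mean / Δ tables, where Δ is the half-range
`(Max − Min) / 2`; `write_results()` emits per-run JSON, the summary CSV
and a boxplot-ready long-format CSV.

There is also a shell interface (`inst/bin/tpsreg`) with `register`,
`phantom` and `benchmark` subcommands; see `?cli_main`.

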