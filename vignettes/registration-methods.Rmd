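---
title: "Membrane-computing registration: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-computing registration: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpsreg)
```

This vignette is the package's own account of its method: the similarity
model and its estimator, the membrane optimizer and its rules, every
tunable that matters, what the synthetic phantoms do and do not emulate,
and the numerical and design choices made where more than one reasonable
option existed.

## The similarity model

Registration seeks the rigid+scale transform of a floating image that
maximizes its mutual information (MI) with a fixed reference:

$$\mathrm{MI}(A,B) \;=\; \sum_{a,b} p(a,b)\,
  \log_2\!\frac{p(a,b)}{p(a)\,p(b)},$$

where $p(a,b)$ is estimated from a joint histogram of intensity levels.
MI is the standard choice for multimodal alignment because it rewards
*statistical* dependence between intensity patterns rather than intensity
agreement — a tissue class may be dark in one contrast and bright in the
other and still contribute fully at correct alignment.

Estimator choices, all surfaced as arguments:

* **Bins.** 64 equal-width bins on $[0,1]$, the last bin right-closed.
  64 bins on a $128^2$ image leaves $\approx 4$ jointly valid pixels per
  occupied cell at alignment — enough resolution to discriminate
  sub-degree rotations without starving the estimator. Coarser binning
  (32) is used in the fast test fixtures.
* **Log base.** Base 2 (scores in bits). The base rescales the objective
  and cannot move any argmax.
* **Overlap handling.** A pixel contributes only where *both* validity
  masks are true. Pixels exposed by a transform are fill-valued and
  masked out; counting them would add a spurious background–background
  dependence that rewards pushing the float off-frame. A transform with
  *no* jointly valid pixels scores 0 — the worst value rather than an
  error — so optimizers can recover from off-frame excursions.
* **Normalization.** Images are min–max normalized to $[0,1]$ per image
  at load time; MI is invariant to monotone rebinning of either marginal,
  so this only standardizes the bin edges.

## The transform and its conventions

A candidate is $(x, y, \theta, Z)$: $x$ pixels **up**, $y$ pixels
**left**, $\theta$ degrees counterclockwise, isotropic scale $Z$ about
the image center $((H{-}1)/2,\,(W{-}1)/2)$, with the fixed composition
*scale → rotate → translate*. Three of these conventions (vertical-first
axis order, positive-up/positive-left translation, and the composition
order) are arbitrary in principle but must be fixed for ground-truth
inverses to be well defined; they are documented at `?transform_params`
and honored everywhere, including `invert_params()`, which returns the
closed-form inverse
$\theta' = -\theta$, $Z' = 1/Z$, and the rotated-and-rescaled negated
translation.

Resampling is inverse-mapping bilinear interpolation: each output pixel
pulls from the inverse-transformed source coordinate; out-of-domain
coordinates (or any masked contributing pixel) yield fill 0 and an
invalid mask entry. Quarter-turn angles use exact trigonometric constants
so that integer translations with $\theta \in \{0,90,180,270\}$ and
$Z = 1$ reduce to pure index permutations, bit-equal to their oracle —
this keeps the geometry testable without interpolation tolerance.

## The tissue P system optimizer

The optimizer is organized as 13 membranes in a fixed three-level tree
(one output membrane, 3 aggregators, 9 leaf membranes), fully connected
by parent–child and same-parent sibling channels. Only the 9 leaves hold
particles (default 10 each); levels 1–2 hold no particles and only
aggregate, so all objective evaluations happen at the leaves.

One **step** comprises, in order:

1. *Evolution* (leaves): each particle's velocity is updated with inertia
   $\omega^t$ plus three stochastic attractions — toward the membrane's
   local best ($l_0$), a uniformly chosen sibling best ($l_1$) and the
   parent's best ($l_2$) — with independent $U(0,1)$ draws per dimension;
   velocities are clamped per dimension, positions clipped into bounds.
   The membrane's local best is then the objective argmax over the new
   positions and the incumbent.
2. *Sibling exchange*: each leaf's neighbor list is overwritten with
   value-copies of its two siblings' current bests (freshest information;
   copies, never moves).
3. *Parent exchange*: parents pool value-copies of child bests and send
   their own best down.
4. *Selection–substitution*: each parent max-selects over its pool and
   incumbent.
5. *Promotion*: the output membrane max-selects over the aggregators.

Every selection keeps the incumbent on ties, which makes all best-score
traces non-decreasing — a property the tests assert at every membrane and
step. The run halts after a fixed step count and returns the output
membrane's object.

### Tunables

| parameter | default | units | rationale |
|---|---|---|---|
| `particles_per_membrane` | 10 | particles | 9 × 10 = 90-particle system, ample for a 3–4-D search box |
| `steps` | 40 | steps | with 10 particles: 3690 evaluations, the benchmark budget |
| `omega_start`, `omega_end` | 0.9 → 0.4 | — | linear decay, the standard explore-then-exploit schedule |
| `l0`, `l1`, `l2` | 1.0 each | — | see below |
| `velocity_clamp` | half the bound width | per-dim | prevents bound-to-bound oscillation |
| `bounds` | ±15 px, ±15°, Z ∈ [0.5, 1.5] | mixed | generous capture range for slice registration; a zero-width row pins a parameter |
| `bins` | 64 | levels | see estimator notes |

**Learning factors.** The three attraction weights are deliberately set
so their sum is 3.0, not the "classic" cognitive+social sum of ~4. With
per-dimension $U(0,1)$ draws, the expected per-step attraction is half
the sum; a sum above ~4 places the particle dynamics in the oscillatory
regime, and we measured exactly that: with $l_i = 1.4$ the optimizer
circles the optimum of even a smooth quadratic at ~$5\times10^{-2}$
error, an order of magnitude worse than with $l_i = 1.0$, and loses a
few millibits of final MI on phantom benchmarks. The flat comparison
swarm uses $c_1 = c_2 = 1.49445$ (the standard constriction-factor
value) for the same reason — its textbook alternative $c_1 = c_2 = 2$
with linearly decaying inertia stalls near $0.4$-pixel error.

**Initialization.** Positions uniform within bounds, velocities zero,
every membrane's initial best taken from its own initial particles. Before
any communication has occurred, the neighbor and parent attractors fall
back to the membrane's own best, which makes the first step well defined.

## The baselines

All optimizers share one contract — an opaque objective closure
`function(c(x, y, theta, Z)) -> score`, a 4×2 bounds box, a config, a
seed — and return the same result shape with a non-decreasing trace.
The GA is real-coded (tournament of 3, BLX-0.5 crossover at 0.9,
Gaussian mutation at 0.1 with sd 0.1 × bound width, elitism of one). The
PSO+Powell hybrid refines the swarm's best point by bracketed
line-minimization along each coordinate (accept-only-improvement;
`tol = Inf` disables refinement and reproduces the plain swarm exactly).
Benchmark comparisons are **budget-fair** by default: swarm iterations
and GA generations are derived from the membrane optimizer's evaluation
budget ($9m(T{+}1) = 3690$ at defaults), with a fixed 500-evaluation
reserve for the Powell stage.

## The phantom generator

`make_phantom()` emulates the shape of a brain atlas slice: a nested-
ellipse head with an outer CSF-like rim, gray- and white-matter
ellipses, and two vertically elongated ventricle-like CSF regions, plus
seeded Gaussian noise (default sd 0.02, a high-but-plausible SNR for a
normalized MR slice). `make_modality_pair()` renders the same label map
under two per-class intensity lookups with independent noise: the
CSF-like class is in the lowest intensity third on the T1-like image and
the highest third on the T2-like image, and white/gray contrast inverts,
so pixelwise intensity agreement fails across the pair while MI at
alignment stays high — the property that makes multimodal registration
non-trivial.

What the phantom does **not** emulate: anatomical detail, bias fields,
partial-volume effects, anisotropic voxels, or any 3D structure. Its MI
landscape is smoother and its optimum sharper than for real atlas data,
so passing recovery tests here demonstrates correctness of the machinery
and sane optimizer behavior — not clinical-grade robustness. One
consequence, computed by the acceptance benchmark itself: on this easy
landscape *every* optimizer reaches the MI ceiling, and the flat swarm's
final polish is marginally (≈0.001 bits) better than the membrane
system's, whose evolution rule keeps membrane-level rather than
per-particle memory and takes 40 sequential steps where the matched-budget
swarm takes 122 iterations. The membrane system's distinguishing behavior
at this scale is its *consistency* — its MI half-range across seeded
repetitions is about half the GA's.

## The benchmark protocol

`run_experiment()` builds the reference and float (via
`make_float()`, which applies a known construction transform and attaches
its exact inverse as ground truth), then runs each requested optimizer
for 8 seeded repetitions (seed of repetition $r$ = base seed + $r-1$, so
any run is individually reproducible). Per run it records the absolute
deviation of each recovered parameter from the ground-truth inverse
(rotation folded modulo 360°) and the final MI; per algorithm it reports
Max, Min, Mean and the half-range $\Delta = (\mathrm{Max}-\mathrm{Min})/2$.
Half-range was chosen as the $\Delta$ semantics because it is the unique
simple statistic consistent with the benchmark tables this protocol
mirrors. The standard constructions are the single-modal pair
$(8, 6, 5°, Z{=}1)$, the scaled variant $(8, 6, 5°, Z{=}0.8)$ (inverse
scale $1/0.8 = 1.25$), and a multimodal variant registering a
transformed T1-like image to the T2-like reference.

Problem sizes used throughout the shipped tests and the acceptance
script: 128×128 phantoms, 64 bins, 10 particles per membrane, 40 steps,
8 repetitions — the package's chosen desk-scale operating point; smaller
fixtures (48–64 px, 32 bins) are used where only contracts, not
accuracy, are under test.

## Numerical choices and degenerate inputs

* Ties in every max-selection keep the incumbent (stabilizes traces and
  makes monotonicity exact, not statistical).
* Tiny negative MI from floating-point cancellation is clamped to 0;
  transpose symmetry is made *exact* by summing the $(i,j)/(j,i)$ cell
  terms as commutative pairs in a fixed traversal.
* A constant reference (MI ≡ 0 against anything) completes the run and
  returns score 0 — degenerate objectives are absorbed, not errors.
* Zero-width bound rows pin a parameter: initialization collapses to the
  bound value and the velocity clamp for that dimension is 0.
* Non-finite particle updates raise an error naming the likely cause
  (bad bounds or clamp), rather than propagating NaNs into histograms.

## Known limitations

2D slices only; rigid+scale only (no shear, no deformation); no
gradient-based refinement of the MI surface (the Powell stage is
derivative-free); the phantom benchmark's difficulty ceiling noted above.
NIfTI input is supported slice-wise, with the slice axis and index chosen
by the caller.
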