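---
title: "Binocularity from anatomical correspondence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binocularity from anatomical correspondence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`evostereo` asks whether depth can be read out without solving the image
correspondence problem. The premise: pair retinal loci by anatomical
position alone. A contrast edge nearer or farther than the horopter
projects to slightly different azimuths in the two eyes, so anatomically
corresponding receptive fields receive different luminance distributions,
and the *difference* in their activity carries the sign and magnitude of
disparity at that retinotopic location. The package builds the minimal
world in which this can be tested, evolves the read-out circuitry with a
genetic algorithm, and measures the evolved units the way a physiologist
would.

This vignette documents the model, every tunable that matters, the
numerical and design choices that were genuinely open, and what the tests
do and do not establish.

## The simulated environment

The world contains luminous fronto-parallel strips (400 cd·m⁻² figure, 1
cd·m⁻² background) seen through pinholes by two 200 × 40-pixel sensor
arrays, 0.01°/pixel (2° × 0.4°). Corresponding pixels share array
coordinates across eyes; azimuth is signed, negative to the left.

* The **fixation strip** spans azimuth [0°, 0.3°] in both eyes and never
  moves: its left edge is the fixated vertical boundary on the midline.
* The **target strip** (and, in the relative stage, the **reference
  strip**) is 0.15° wide with its eccentric (left) edge at −0.3° (−0.6°)
  and its body extending toward the fovea. Depth is parameterized directly
  as signed disparity `d` in degrees (positive = uncrossed = far); the
  strip is translated by −d/2 in the contralateral (left) eye and +d/2 in
  the ipsilateral eye. Metric depth and interocular distance are never
  needed: they only enter through this angular displacement.

Two choices here were open and deserve their rationale:

* **Strip orientation.** Only the strip's edge position is constrained by
  the scene description; the body could extend foveally or eccentrically
  from it. We render the body on the foveal side. Under pinhole geometry a
  far surface in the left visual field displaces its left-eye image
  leftward (eccentrically); with the body on the foveal side this *raises*
  the contralateral ON-center unit's activity with increasing far
  disparity, which is the configuration in which far-coding units can
  evolve contralateral excitation through non-decreasing sigmoids. The
  mirror-image orientation produces the mirror-image circuit.
* **Strip width 0.15°.** Wide enough to cover the 0.12° receptive-field
  center with margin, narrow enough that a strip's trailing edge stays
  outside the neighbouring unit's center. The trailing edge does intrude
  into the neighbouring unit's *surround* at some disparities; the
  consequences are discussed under limitations.

Sub-pixel edge positions are rendered by area-weighted anti-aliasing of the
edge column, so disparity is continuous on the 0.01° grid; coverage
fractions within 10⁻⁹ of 0 or 1 are snapped so that whole-pixel
displacements yield exactly binary images (anti-correlation is only defined
for those). Figure area is conserved across the two eyes for every
disparity, and zero disparity renders the two eyes identically — both are
tested properties.

Stimulus banks (`make_absolute_bank`, `make_relative_bank`,
`make_control_bank`) store scene parameters, not pixels; pairs are rendered
on demand and regeneration from `(kind, parameters, seed)` is
bit-identical. Disparity magnitudes are drawn uniformly on (0, 0.18°]; the
relative bank draws target and reference disparities independently and
uniformly on [−0.18°, 0.18°] and rejection-samples the requested sign of
their difference, which realizes the three surface configurations
(both-far, straddle, both-near) in proportions 1/4 : 1/2 : 1/4. The
uniform law is our choice; nothing in the scene description fixes the
training distribution of depths.

## The fixed monocular front end

Each probed azimuth carries one ON-center/OFF-surround unit per eye at
identical array coordinates: a 3 × 3 grid of 12 × 12-pixel subregions
(0.36° field; 0.12° center). The mean luminance of each block, normalized
by the figure luminance so drives live in [0, 1], passes through a preset
sigmoid `Post = ±A / (1 + exp(−B·Pre + C))`; the final output sigmoid
(A 0.9771, B 5.7152, C 1.7300) compiles the nine transforms. The transfer
function is read as the standard logistic; gain `A` is kept non-negative
and excitation/inhibition is carried by an explicit sign, so connection
classification is well defined.

The nine subregion parameter sets are preset, not evolved. Defaults:
center (A 1, B 6, C 1.5, +), each surround block (A 1/8, B 6, C 1.5, −).
The surround gain of 1/8 makes total surround inhibition balance center
excitation, the standard center–surround balance; with unit surround gains
the eight OFF blocks pin the output sigmoid deep in saturation and the unit
is effectively mute (dynamic range below 10⁻², too small for any
downstream read-out), so balance is not cosmetic. All nine sets are
configurable (`default_subregion_params`, `config_objects`) so alternative
presets can be dropped in.

With these defaults the unit's activity over target disparity is monotone,
rising from ≈ 0.03 to ≈ 0.74 for the contralateral eye as far disparity
grows, and saturating once the displacement exceeds the center half-width —
the origin of the emergent disparity limit measured later. The vectorized
bank-activity path exploits the vertical uniformity of the scenes (strips
span the full array height) and is tested to 10⁻¹² against a scalar
per-pixel oracle.

## Evolvable binocular units

A **second-order** unit sums four evolvable sigmoid transforms of the
monocular activities, in the fixed input order (contra@fixation,
ipsi@fixation, contra@target, ipsi@target); its value is read as absolute
disparity in degrees. Far- and near-coding units evolve separately, each
trained on its polarity's magnitude. A **third-order** unit sums four
evolvable sigmoids of the second-order responses (far@target, near@target,
far@reference, near@reference) and is trained on relative-disparity
magnitude; the evolved second-order genomes are frozen, and the clone at
the reference position shares the target genome verbatim, differing only
in which monocular pair feeds it (the fixation inputs are shared).

Second-order responses are a disparity code spanning only ≈ 0–0.14
degrees. Before entering third-order sigmoids they are divided by the
0.18° disparity ceiling of the environment, so every evolvable stage
receives drives of order unity, exactly as subregion luminances are
normalized by the figure luminance. Without this, sigmoids initialized
with slopes of order 1–10 are flat across the third-order input range,
selection has no gradient, and the relative stage cannot evolve at all.

Genomes are initialized weak but fully connected (A ~ U(0, 0.1),
B ~ U(0, 10), C ~ U(−5, 5), equiprobable signs) and serialize to JSON with
full precision (a serialization round trip reproduces probe curves to
10⁻¹²).

## The genetic algorithm

Per generation and population: a fresh seeded 200-stimulus bank; lifetime
error `Σ |response − disparity|` for every network (monocular activities
computed once per bank and shared — a pure, bit-equivalent optimization);
success scores `max(error) − error` (uniform fallback when all errors tie);
roulette selection implemented with cumulative sums over half-open
intervals (boundary draws go to the higher index, zero-width sectors are
never hit); parameter exchange (each individual, with probability 0.8,
swaps each scalar with a uniformly chosen partner with probability 1/2 —
exchange conserves the population-wide multiset of every parameter row,
tested exactly); then Gaussian mutation. There is no elitism.

Mutation is the one operator the scheme needs beyond the description
above: pure exchange can never produce parameter values absent from the
initial population. Defaults: per-parameter probability 0.02, standard
deviation 5 % of the parameter's allowed range, clipped to bounds; signs
flip with the same probability. The bounds are A ∈ [0, 0.5], B ∈ [0, 10],
C ∈ [−5, 5]. Two of these are deliberate:

* **A ≤ 0.5.** Gains must grow past their weak initialization (0.1) for
  responses to span the trained range, but a cap of half-unity means no
  single connection can span the third-order code range (up to 0.36°), so
  coding has to be shared across input lines — the distributed,
  antagonistic arrangement the model is about. We also examined A ≤ 1;
  it trades distributed coding for single-line solutions and was rejected
  on that structural ground.
* **B ≥ 0.** The transfer stays non-decreasing; inhibition is carried by
  the discrete sign, keeping "excitatory vs inhibitory" interpretable.

Reproducibility: a single master seed is split deterministically into
per-population seeds and per-generation bank seeds
(`(seed·48271 + index·1299721) mod (2³¹ − 57) + 1`); bank generation
restores the caller's RNG stream, and an identical configuration and seed
reproduce a run bit-for-bit (tested).

## Probes

* **Tuning curves** render each probe disparity, run the forward pass for
  one best genome per population, and aggregate mean ± SD across
  populations. Anti-correlated mode inverts the contrast of one eye and is
  restricted to whole-pixel grids (0.02° steps) where images are binary.
* **Ocular dominance** is response-based: each eye is probed alone (its
  strips swept over ±0.09°, the other eye uniform background) and
  `ODI = (M_c − M_i)/(M_c + M_i)` from the peak-to-trough modulations.
  Weight-based indices were rejected because evolved sigmoid nonlinearity
  makes raw gains incomparable. A silent unit returns ODI 0 with a
  degenerate flag.
* **Connection classification** measures each connection's contribution
  swing over the conventional sweep; a swing under 1 % of the unit's total
  response range is "negligible", otherwise the connection's sign labels
  it excitatory or inhibitory.
* **Disparity limit**: the largest probed magnitude at which the median
  coding error across populations stays within 0.02°. This is an
  operationalization of "the largest disparity reliably encoded"; no
  closed-form rule exists for it, and both the grid (0.01°) and tolerance
  are configurable.
* **Preferred depth** for the dominance–tuning correlation is the
  disparity of maximal response on the conventional curve.
* **Retinotopy control**: a run whose target position is randomized per
  stimulus is compared against a fixed-position run; a run counts as
  "evolved" only if its final median error beats 0.8 × the error of the
  best label-independent constant responder on its own stimulus
  distribution.
* For the anti-correlation comparison we invert each polarity's *dominant*
  eye (contralateral for far-tuned, ipsilateral for near-tuned units).
  Inverting the non-dominant eye of a monocularly dominated unit leaves
  its tuning largely intact and tests nothing about contrast dependence.

## Problem sizes, and what the tests show

The package's analyses and tests use a reduced regime — 5 populations ×
200 networks × 600 generations with 200-stimulus lifetimes — chosen so a
complete replication (both absolute polarities, both relative polarities,
and the retinotopy control) runs in a few minutes on one core. The full
regime (20 × 500 × 2,500) is the configuration default.

At the reduced scale, with the shipped seeds, the suite computes:

* held-out absolute-disparity error of the best evolved genomes below
  0.02° (median across populations, within the evolved limit), against a
  random-initialization baseline an order of magnitude worse;
* an operational disparity limit of 0.14–0.15°, below half the 0.36°
  receptive-field width, emerging from center–surround geometry rather
  than being imposed;
* a conventional response range topping out near 0.13–0.15;
* contralateral dominance of far-tuned and ipsilateral dominance of
  near-tuned second-order units in ≥ 80 % of populations;
* anti-correlated responses with reversed tuning slopes at strongly
  reduced amplitude;
* a "failed" verdict for position-randomized training next to an
  "evolved" verdict for fixed-position training.

## Known limitations

* **Partner-connection redundancy.** On the trained side of the horopter a
  *single* monocular activity is already a monotone function of disparity,
  so the second informative input to a second-order unit is largely
  redundant; selection on it is close to neutral, and across replicate
  populations it often drifts to "negligible" rather than settling as the
  inhibitory partner. The contralateral-excitation (far) and
  ipsilateral-excitation (near) halves of the signature are robust; the
  full antagonistic pair is not, at this scale.
* **Third-order precision.** The four-sigmoid family over the frozen
  second-order streams can represent relative disparity with error well
  below the level the reduced-scale GA actually reaches (≈ 0.05° mean
  absolute error). The limiting factor is the selection scheme itself:
  fitness-proportionate roulette exerts weak pressure, and the heavy
  per-scalar exchange keeps breaking up co-adapted parameter triplets, so
  the population equilibrates above the family's representational floor
  regardless of generations. Greedy hill-climbing from the evolved state
  keeps improving, confirming the gap is search, not representation. The
  evolved units still reduce error roughly three-fold from baseline and
  preferentially adopt the antagonistic excitation pattern (excited by
  far@target and near@reference for relative-far units), but per-class
  precision and full-pattern consistency fall short of the full-scale
  regime's description; the corresponding study-condition tests fail by
  design and document this.
* **Anti-correlated offset sign.** The *shape* of anti-correlated tuning
  (small, slope-reversed) is reproducible; the sign of its small constant
  offset is not pinned down by the model, because it depends on the
  cancellation structure each population happens to evolve at the
  untrained zero-disparity point.
* **Surround crosstalk.** A depth-varying strip can intrude into the
  surround of the neighbouring position's unit (reference strip into the
  target unit's field, target strip into the fixation unit's field). This
  gives fixation-position inputs a weak disparity dependence and makes
  far@reference partially redundant for third-order units. It is a
  geometric consequence of 0.3° spacing with 0.36° fields, not a bug; the
  probes measure the circuit that evolution actually finds in this world.
* **What the generator does not emulate.** Constant-width strips (a real
  surface's image size varies with depth), no natural images or random-dot
  stereograms, no vertical disparity, occlusion, or temporal dynamics, and
  published subregion presets that are not recoverable are replaced by the
  balanced defaults above. Passing tests therefore show that the
  anatomical-correspondence read-out works and evolves in this minimal
  world; they do not show that it survives natural image statistics.

## Reproducing a full analysis

```{r}
library(evostereo)

cfg <- evolution_config(scale = "desk", master_seed = 1)
run_far <- evolve_absolute(cfg, "far")
run_near <- evolve_absolute(cfg, "near")

assembly <- run_far$assembly
curves <- list(tuning_curve(best_genomes(run_far), assembly),
               tuning_curve(best_genomes(run_near), assembly))
disparity_limit(curves, tolerance = 0.02)

frozen <- list(far = best_genomes(run_far)[[1]],
               near = best_genomes(run_near)[[1]])
run_rel <- evolve_relative(cfg, "rel_far", frozen)

control <- evolve_absolute(cfg, "far", bank_kind = "control")
retinotopy_control_report(control, run_far)
```
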