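---
title: "Modelling multimodal learning walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multimodal learning walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(learnwalk)
```

Before their first foraging trips, ants perform *learning walks*: short
loops around the nest entrance, punctuated by pirouettes in which they
scan the panorama.  Across successive walks the loops expand by
characteristic fold-increases, and the memories laid down during them
later support visual homing.  `learnwalk` implements an agent that
reproduces this behaviour from the interplay of three cues — mushroom-body
visual familiarity, innate chemotaxis on a nest-centred odour field, and
noisy path integration — fused step by step into a single *Learning
Vector*.  This vignette describes the model, the choices behind every
tunable parameter, and what the simulations do and do not show.

## The model in brief

At position $(x, y)$ with step size $U$ the agent computes:

* visual familiarity $\omega_v = 1 - C_\mathrm{MBON}/N_\mathrm{active}$
  from the mushroom-body novelty score of the current view, and a visual
  direction $\theta_v$ maximising the novelty *decrease* over sampled
  neighbouring positions;
* olfactory familiarity $\omega_{olf} = C(x,y) =
  \exp(-(x^2+y^2)/2\sigma^2)$ and the up-gradient direction
  $\theta_{olf} = \mathrm{atan2}(-y, -x)$;
* the path-integration direction $\theta_{PI}$ (the antipode of the
  accumulated outbound vector) with fallback weight
  $\omega_{PI} = \max(1 - \omega_v - \omega_{olf},\, 0)$.

The Homing Vector is $\sum_i \omega_i(\cos\theta_i, \sin\theta_i)$.  Three
monotone familiarity-to-offset mappings (each into $[0, \pi]$) produce the
exploration offset
$\phi = A_c\,(\omega_v F_v + \omega_{olf} F_{olf} + \omega_{PI} F_{PI})$,
clamped to $[0,\pi]$; rotating the Homing Vector by $\phi$ yields the
Learning Vector, whose direction the agent follows (with probability
`p_rand` it instead takes a stochastic von Mises step).  When the walk's
step budget $np_j = np_1 \cdot r^{j-1}$ is spent, $A_c = 0$ and the agent
homes until it re-enters the nest radius.

## The synthetic environment

`generate_terrain()` scatters cone-shaped landmarks (height 1–4 m)
uniformly in an annulus 8–20 m from the nest, leaving the 10 m-half-width
arena itself an open clearing; `render_panorama()` ray-casts a 90 × 25
binary sky/object panorama (ground below the horizon at 0.5) from 5 mm
eye height, elevations −10° to 60°.

The landmark *distance* is the load-bearing choice.  Snapshot familiarity
generalises over roughly the parallax scale of the scene: with landmarks
underfoot the visual code decorrelates within centimetres, the familiarity
field degenerates into narrow ridges along the walked loops, and displaced
agents trap on the ridge of their last walk instead of descending to the
nest.  With distant landmarks the panorama changes smoothly over metres,
the accumulated depression forms a single monotone familiarity bowl
centred on the nest — MBON activity then falls rather uniformly over the
whole arena as learning progresses, which is exactly the regime the
original experiments describe — and gradient homing works across the full
1–8 m test range.  Real learning-walk habitats (clearings surrounded by
grass tussocks, shrubs and trees) have the same structure.

What the generator does **not** emulate: texture, lighting and
within-object detail; wind-structured odour plumes (an anisotropic
stretched-Gaussian hook exists, `odour$wind`, but the nominal experiments
use the isotropic field); 3D motion (agents move in the plane).  Passing
tests therefore demonstrate the *mechanism* under clean geometric cues,
not performance on natural imagery.

## The visual front end

Views are encoded as Zernike-moment amplitudes ($n_{max} = 16$, hence 81
features matching the VPN count).  The production path evaluates the
moments by polar quadrature directly on the panorama grid (azimuth =
polar angle, elevation = radius), which makes the amplitudes *exactly*
invariant under integer azimuth-bin shifts, i.e. under changes of viewer
heading; a Cartesian unit-disk raster path (`preprocess_panorama()` /
`zernike_amplitudes()`) is provided for direct inspection and is
rotation-invariant to ~1e-3.

Three further choices shape the KC code, each made because the plain
alternative demonstrably destroys the memory's spatial selectivity:

* the rotation-symmetric ($m = 0$) amplitudes are excluded from the MB
  input (config `mb$use_m0`): they encode overall skyline energy, are
  nearly position-independent, and mask the bearing-pattern code;
* amplitudes are log-compressed relative to the spectrum median before
  min-max normalisation, so the mid-spectrum pattern rather than the few
  globally dominant amplitudes drives KC competition;
* KC activation (mean connected input above $\theta_{KC} = 0.04$) is
  capped winner-take-all at the strongest 2 % of the 4000 KCs
  (`mb$kc_sparsity`), the sparsity-control role attributed to APL-like
  inhibition.  A fixed-size active set keeps MBON scores comparable
  across views.

Learning depresses active KC→MBON weights subtractively
($w \leftarrow \max(0, w - \lambda_{vis})$, $\lambda_{vis} = 0.01$) once
per pirouette, on the centre view only.

## Parameters

| group | parameter | default | why |
|---|---|---|---|
| odour | `sigma` | 0.2 m | olfaction effective only within the first walks' range (~0.24 m), mid of the stated 0.15–0.25 band |
| mb | `n_vpn`, `n_kc`, `theta_kc` | 81, 4000, 0.04 | network dimensions of the reference parameter table |
| mb | `lambda_vis` | 0.01 | low end of the stated 0.01–0.018 range; larger values saturate the weight floor over four walks and *degrade* the walk-4 memory |
| mb | `fan_in`, `kc_sparsity` | 10, 2 % | standard sparse-MB practice |
| mb | `scan_step` | 0.3 m | radius of the pirouette's directional novelty sampling; at the 1 cm step size the novelty differences are quantisation noise |
| pi | `noise_sd` | 1e-4 m | 1 % of the step length per component |
| pi | `schedule` | d1 = 0.184 m × (3.8, 2, 2) | empirical first-walk maximum and fold-increases |
| pi | `fpi_form`, `fpi_grace` | complement, 0.75 | see below |
| lv | `sign_mode`, `sign_repeat` | persistent, 0.75 | rotation sign kept across scans with p = 0.75, flipped otherwise: one-sided rotation (`"ccw"`) precesses around the nest and inflates walk-4 hulls ~2×, per-scan random signs confine walks to narrow sectors; the persistent mix reproduces both the two-sided loops and the observed hull areas |
| agent | `U` | 0.01 m | step length |
| agent | `p_rand`, `kappa` | 0.6, 20 | stochastic-step probability and concentration, inside the stated 0.2–0.8 / 5–50 ranges |
| agent | `np1`, `growth` | 120, 2 | first-walk step budget; with the leash below this yields first-walk excursions in the 0.12–0.25 m band |
| agent | `scans_per_walk` | 10, 15, 20, 25 | growing pirouette counts (the source values are unpublished); fewer early scans weaken the interior of the familiarity bowl enough to break walk-4 homing |

Parameters published only as ranges were fixed once, by a single sweep
against the trajectory anchors the original model was itself tuned to
(the per-walk excursion and coverage bands), and not revisited.

### The PI offset mapping

The printed form of the PI familiarity ($r/d_k$, scaled to $[0,\pi]$)
makes the offset *grow* with the excursion: the agent spirals outward
until the step budget ends, first-walk maxima overshoot the empirical
band ~5×, and — because $d_k$ grows faster than the step budget — later
walks *shrink*.  The unscaled literal form pins every walk at ~0.2 m.
Neither can produce the 3.8×/2×/2× expansion.  The default therefore
reads PI familiarity as the walk's *remaining exploration licence*
$1 - r/d_k$, mapped piecewise-linearly onto $[0, \pi]$ (full licence up
to `fpi_grace` = 0.75 of $d_k$, then declining to zero).  This keeps all
three mappings monotone in familiarity and makes the $d_k$ schedule act
as a leash, which is what generates the observed expansion.  Both printed
variants remain available (`pi$fpi_form = "ratio"`, `pi$fpi_scaled`).

## Displacement tests

`homing_test()` releases an agent with a frozen memory at 64 points
(1–8 m × 8 bearings).  A displaced agent has no valid PI home vector, so
the PI weight is forced to zero and the remaining weights renormalised;
$A_c = 0$ (no exploration offset); scans are replaced by learning-free
visual-direction refreshes every 10 steps (EMA-smoothed across
refreshes).  Two further rules matter:

* **confidence floor** (`test$min_cue` = 0.12): the agent only steers by
  its cues when $\omega_v + \omega_{olf}$ exceeds the floor — an agent
  with a near-naive memory wanders instead of beelining along noise.
  This is what makes homing success *experience-dependent*: after one
  walk the depression contrast rarely clears the floor, after four it
  does across most of the near range.
* **budget and stall**: trials end at success (within 0.1 m of the
  nest), after 1500 steps, on leaving the release distance + 2 m, or
  after 500 steps without improving the best approach by 2 cm (a lost
  agent's wander).  All configurable under `cfg$test`.

## Numerical choices

Azimuth convention CCW from +x, angles wrapped to $(-\pi, \pi]$.
Degenerate cases: an undefined cue direction (at the nest, or a zero PI
vector) contributes nothing to the Homing Vector; a (near-)cancelled
Learning Vector keeps the previous heading; ties in the directional
novelty scan break uniformly at random; a novelty-trace window with
fewer than 3 entries or zero spread maps to the neutral offset $\pi/2$;
the world boundary reflects.  All generation and simulation is
deterministic given the master seed (per-agent and per-walk sub-seeds
are derived from it).

## Problem sizes

The shipped experiments use the study scale: 10 agents × 4 walks
(np = 120…960 steps), 64 release points × 2 experience levels, and
matched-seed cohorts for the species comparison; the acceptance script
runs the lot in a few minutes on one CPU thanks to the C++ renderer
(per-column plane-clipping, exactly equivalent to per-pixel ray casting)
and the fused C++ MB forward pass.  Unit tests run on a reduced world
(12 near landmarks, 800 KCs, 30-step walks).

## Known limitations

* The coverage-area statistics sit slightly wide of the empirical bands
  at walk 4 (hulls ~6 % above the upper band on average): the model's
  late walks sweep slightly broader sectors than real ants, whose area
  fold-increase (2.5×) lags their distance fold-increase (2×).
* The walk-4 vs walk-1 homing effect size varies more across master
  seeds (d_z ≈ 3–6) than the reported 2.8: with a clean synthetic
  familiarity bowl the improvement can be more uniform across agents
  than in the original setting.
* Learning is imposed to end after four walks; no autonomous
  transition to foraging is modelled, and no olfactory learning (the
  odour field is innate).
* The exploration-offset fusion is algebraic; no neural implementation
  of the ring-attractor hypothesis is attempted.
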