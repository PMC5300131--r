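---
title: "Modeling emphysema progression and lung volume reduction in an elastic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling emphysema progression and lung volume reduction in an elastic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lvrnet)
```

## The model

lvrnet represents a two-dimensional sheet of lung parenchyma as a
pre-stressed network of linear springs on a hexagonal lattice, each hexagonal
cell standing in for one acinar airspace. The total energy of a
configuration is

$$E_{tot} = \sum_i \tfrac12\, k_i\, \Delta l_i^2 \;+\; \sum_j g\, n_j\, y_j,$$

the elastic sum running over unbroken springs ($k_i$ the spring constant,
$\Delta l_i$ the displacement from resting length) and the second term a
gravitational potential in which each node carries a downward load
proportional to the number of dependent nodes below it in its template
column. Spring constants and resting lengths are drawn from uniform
distributions (mean ± SD of 1.0 ± 0.4 and 0.5 ± 0.1; the uniform half-width
is $\mathrm{SD}\sqrt3$ so the realised SD equals the declared one). Because
the undeformed strut length is 1 while resting lengths average 0.5, fixing
the perimeter leaves the interior taut: the network is pre-stressed, as
parenchyma is at functional residual capacity.

### Lattice construction

The default template generates 56 horizontal zigzag chains of 85 nodes with
vertical struts on alternating interior columns — exactly 4,760 nodes in an
85 × 56 array, 6,987 unit-length elastic elements, and a nominal 42 × 55 =
2,310-cell template with a straight, clipped, fixed perimeter. These three
counts cannot be reconciled with a fully closed honeycomb by Euler's
formula; the clipped zigzag grid is the unique convention we found that
satisfies all of them simultaneously, and it is what `build_hexagonal_network()`
implements. Cells on the straight boundary are clipped (open toward the
frame) and are counted by the template, not by the airspace labeling.

### Gravity

Gravity's role here is a weak, persistent bias of mechanical load — and so
of rupture — toward the upper network. The constant `gravity_g` defaults to
$0.28/\mathrm{hex\_cols}^2$: per-node loads stay near or below ~1% of the
mean spring tension, while the load accumulated down a column raises
top-zone tension by roughly 30% of the mean. In ensemble probes this moves
about two thirds of progression ruptures into the upper third of the
network without dominating the force heterogeneity. The height-squared
scaling keeps that relative bias the same at any lattice size. Dependent
node counts are assigned once on the intact lattice and frozen; the load is
a static body-force proxy for a long-time-scale effect, not a dynamic
force balance.

## Energy minimization

`minimize_energy()` implements a force-directed simulated-annealing
variant: each free node in turn is proposed a displacement proportional to
(and in the direction of) the resulting force on it; downhill moves are
accepted, uphill moves with probability $\exp(-\Delta E/T)$, and $T$ is
cooled by `cool_factor` (0.95) per sweep from `T0` (by default $10^{-3}$ of
the initial energy). Because the per-spring energy is local, $\Delta E$ is
computed exactly from the node's incident springs only.

Numerical choices that matter:

* **Step size.** The default proposal gain is per-node,
  $1.7/\sum k_{\mathrm{incident}}$ — an over-relaxed, locally scaled step.
  A single global displacement-per-unit-force converges poorly once rupture
  makes the local stiffness heterogeneous; the local gain keeps convergence
  uniform across intact and damaged regions. A global `step_gain` can still
  be supplied.
* **Convergence.** Sweeping stops when the relative energy change per sweep
  stays below `conv_tol` ($10^{-9}$) for three consecutive sweeps, or at
  `max_sweeps` (5,000). The tolerance was set so that the residual force on
  free nodes of the intact default network falls below $10^{-3}$ of the
  mean spring tension.
* **Orphans and debris.** Free nodes whose springs are all broken are
  frozen. So is any connected cluster of free nodes with no path to a fixed
  anchor: under the gravity load such debris has no equilibrium (it would
  fall indefinitely) and, left free, corrupts every downstream energy
  difference. Frozen debris contributes a constant to the energy and
  cancels from all strain derivatives.
* **Determinism.** Sweep order is reshuffled each sweep from the schedule
  seed by a self-contained 64-bit generator, so a (network, schedule, seed)
  triple reproduces bit-identical results on any platform, independent of
  R's RNG state.

## Disease progression

Emphysema is initiated by breaking `round(0.04 × n_springs)` springs chosen
uniformly (279 at full scale), then advanced in stages: springs are ranked
by tension magnitude at equilibrium, the top 0.7% (ceiling, ties by spring
id) become rupture candidates, and each breaks independently with
probability 0.40 before the network re-equilibrates. Five stages are the
default course. Magnitude rather than signed tension is used for ranking so
that strongly compressed struts can also fail; surviving springs carry no
fatigue memory. Rupture concentrates at crack tips, so damage coalesces
into enlarged airspace clusters — the structural signature the airspace
metrics quantify.

## Interventions

**LVRS** (`apply_lvrs()`) removes all tissue strictly above the resection
line at 70% of the current height. The ragged cut edge is *stretched* onto
the line: every surviving node that held an unbroken spring into the
removed tissue is raised to the line and fixed, forming a continuous
horizontal border and loading the border springs. We chose the stretch
semantics (over, say, truncating cut springs tension-neutrally) because it
is what creates the high-force border elements whose appearance
distinguishes effective resection, and it reproduces the immediate
compliance recovery far better. Removed elements are logged but are not
ruptures: they never enter the cumulative broken-element count, which is
reported against the original element total.

**bLVR** (`select_affected_regions()` + `apply_blvr()`) targets enlarged
airspaces: every labeled airspace larger than `min_area_factor` (3) times
the intact cell area qualifies, uncapped by default — three coalesced acini
is the smallest cluster we treat as an emphysematous lesion, and treating
all lesions mirrors a procedure that seals every accessible affected
region. Member nodes move toward the region centroid by
$\sqrt{\mathrm{target\_fraction}}$ (so area scales by the target fraction);
regions touching a fixed border compress only perpendicular to it, toward
the border line, so fixed nodes never move. Reduced nodes are pinned
afterwards, modeling collapsed, sealed tissue. Both interventions and the
untreated projection branch from the identical pre-treatment snapshot.

## Metrics

* **Stress** $\sigma$: central difference of $E_{tot}$ under ±1% biaxial
  strain about the configuration, normalised by the bounding-box area.
  Strain is boundary-driven: all nodes are scaled affinely about the
  bounding-box centre, then free nodes re-relax by deterministic
  zero-temperature descent.
* **Bulk modulus and compliance**: $\sigma$ is evaluated over one
  sinusoidal strain cycle of amplitude 4% (8 points; the stress–strain
  relation is linear to ~$10^{-5}$ relative, so denser sampling does not
  move the slope); $B$ is the least-squares slope, $C = 1/B$, and both are
  reported as percent changes from the intact baseline.
* **Airspace structure**: unbroken springs are drawn one pixel wide at 16
  px per unit length (32 px across a cell diameter — coarse enough to be
  fast, fine enough that the one-pixel strut bias on enclosed areas stays
  under 10%); enclosed background regions are labeled by 4-connectivity;
  `CV_area` is the population coefficient of variation of the pixel areas.
  Regions touching the raster frame (outside the hull, or boundary cells
  opened by rupture) are excluded.
* **β**: `CV_area` restricted to airspaces whose *centroid* lies below the
  planned resection line of the pre-treatment configuration (centroid
  membership was chosen over any-pixel membership; for the large merged
  airspaces that dominate β the two differ only when a lesion straddles
  the line).
* **Force distribution**: population CV and third-standardised-moment
  skewness of tension magnitudes; a degenerate all-equal distribution has
  skewness 0 by convention.
* **Power-law tails**: log-spaced bins (30 per decade of range), densities
  normalised to unit area, and a count-weighted least-squares line through
  the non-empty bins above the mode. The count weights matter: unweighted
  fits let Poisson noise in sparse far-tail bins bias the exponent shallow
  by ~0.1–0.2.

All CVs and skewnesses use population (not sample) moments; every metric
function is pure, so repeated calls on a snapshot agree exactly.

## Outcomes

Survival is the cumulative ruptured-element count at which the compliance
increase first reaches 60%: interpolated linearly when the crossing is
observed, otherwise extrapolated by a second-order polynomial fitted to the
trajectory. When that quadratic is concave-down and never reaches the
threshold — common for short post-treatment arms — the secant through the
trailing three points extrapolates instead; an arm is only flagged failed
if even that slope is non-positive. The failure rate is the compliance
increase over four progression steps, anchored at the first post-treatment
stage (treated) or the post-initiation stage (untreated). Relative benefit
integrates the gap between the 60% threshold and the compliance curve from
the treatment point (where the arms diverge) to each arm's crossing, by
trapezoid over observed stages plus the fitted extrapolation segment, and
normalises the treated area by the untreated one. Integrating from the
divergence point rather than from zero is deliberate: the shared
pre-treatment segment would otherwise enter numerator and denominator alike
and compress every ratio toward 1. Networks split into responders
(β < 3.5) and marginal responders (β ≥ 3.5; ties marginal).

## The study harness and what the generator does (not) emulate

`run_study()` builds `n_networks` lattices with per-network seeds derived
deterministically from one master seed, runs the pre-treatment course,
records β, branches every arm from the shared snapshot with arm-specific
sub-seeds, and aggregates group means ± SD. Identical configuration and
master seed give byte-identical output files; arm failures are recorded and
skipped rather than aborting the study.

The generator emulates inter-subject variability solely through the random
spring parameters and rupture draws on a fixed rectangular template. Real
parenchyma differs in ways the tests deliberately do not probe: irregular
3-D geometry, airway tethering and collateral ventilation, inflammatory
remodeling kinetics, and any calibration of broken-element counts to
clinical time. A passing suite therefore certifies the mechanics,
measurement, and bookkeeping of the model — not clinical validity.

Problem sizes used by the shipped checks: unit tests run on templates
between 1 × 1 and 8 × 10; the qualitative ensemble uses five networks at
12 × 16; the reference study runs the full 42 × 55 template with N = 14
networks and all treatment arms (a few minutes of CPU); determinism is
checked on two 6 × 8 networks end to end.

## Known limitations

* The full-scale ensemble reproduces the qualitative treatment ordering
  and several reference magnitudes, but free parameters the model leaves
  open (annealing schedule, gravity constant, region-selection rule, raster
  resolution) shift the outcome indices; the acceptance report states the
  configuration used alongside every number.
* Near total structural failure (a crack spanning the network) the bulk
  modulus approaches zero and compliance percent changes grow without
  bound; downstream summaries treat such arms like any other, so a single
  torn network can dominate an ensemble mean.
* The rasterized airspace areas carry a resolution-dependent strut bias
  (under 10% at the default 16 px/unit); β and `CV_area` comparisons should
  use a fixed resolution.
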