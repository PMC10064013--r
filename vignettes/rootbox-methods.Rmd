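---
title: "rootbox: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rootbox: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootbox)
```

This vignette is the package's own account of what it simulates, which
choices were genuinely open, and how the packaged calibrations were obtained.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The growth model

A root system is a forest of axes classified by **branching number**
(centrifugal order): primaries emerging from the rhizome are order 0, and
every lateral is one order above its parent. Each order, in each split-root
compartment, has its own parameter set (`growth_params()`):

| parameter | units | meaning |
|---|---|---|
| `r_mean`, `r_sd` | cm day⁻¹ | elongation rate of an axis |
| `lmax_mean`, `lmax_sd` | cm | maximum axis length |
| `la` | cm | unbranched zone at the axis base |
| `lb` | cm | unbranched zone behind the tip |
| `ln_mean`, `ln_sd` | cm | interval between lateral branch sites |
| `theta_mean`, `theta_sd` | degrees | axial insertion angle of new axes |
| `maxB` | – | initial primary count (order 0 only) |
| `radius` | cm | axis radius (surface area = 2πrL) |
| `linear_density` | g cm⁻¹ | dry mass per length |
| `tropism_sigma` | degrees | heading noise per 0.1-cm segment |

An axis elongates at its realized rate until it reaches its realized maximum
length — a constant-rate, hard-capped growth law. A negative-exponential
deceleration is a common alternative in root architecture models; here the
capped-linear law is the primary behaviour because it makes the deterministic
limit exactly enumerable (`min(r·t, lmax)` per axis, site emergence times
`(site + lb)/r`), which the test suite exploits as a closed-form oracle.

**Zone semantics.** `la` is the *basal* unbranched zone (at the root base,
nearest the insertion point) and `lb` the *apical* one (behind the growing
tip). Some architecture models attach these names to the opposite ends;
users porting parameters from other tools should check this deliberately.

**Branch activation.** Sites sit at arc lengths `la + i·ln` (i = 0, 1, ...)
along the parent. A site emits its lateral at the exact moment the parent's
length first reaches `site + lb`, so the zone behind the tip is branch-free
at all times, and a site at `site + lb = lmax` does activate when the axis
reaches full length. There is no extra emergence-delay parameter. Because
emergence times are continuous functions of the parent's realized rate,
branch counts do not depend on the stepping pattern used to advance the
clock; with all standard deviations at zero the whole architecture is
step-size invariant (a tested property).

**Stochasticity.** Per-axis (r, lmax, ln) are normal draws censored below at
1% of the mean; censoring (rather than rejection sampling) keeps exactly one
RNG draw per parameter, so a seed fully determines a simulation given the
call schedule. At the packaged standard deviations the censored mass is
negligible (the Monte-Carlo mean tests would detect any bias). Insertion
angles are drawn per emergence event: axial from Normal(θ, sd) clamped to
[0, 180), radial uniform.

**Geometry and tropism.** Axes are polylines in a box of 20 × 27 × 107 cm
(x, y, depth z; z positive downward), split by a barrier at x = 0 below a
4-cm planting gap. Each 0.1-cm segment's heading is the previous heading
pulled toward the vertical by a fixed fraction (`gamma = 0.15`) and
perturbed by a Normal(0, `tropism_sigma`) angle in a uniformly random
azimuth; segments that would leave the box or cross the barrier are
deflected (heading component reflected), and a convex fallback step toward
the compartment interior handles corner cases. The tropism layer is
geometric plumbing for 3D realism: it changes *where* roots go, never how
long they are — arc length per step is exact, and the tests assert arc
length equals reported length to 1e-6. Whether the emulated study's model
perturbed headings at all is not stated in its methods; this layer is our
own construction.

**Compartments.** Each compartment's root system is simulated with its own
calibration, planted 1 cm inside its side of the barrier. Laterals inherit
the compartment of their parent; the barrier makes crossings impossible
below the gap, which the confinement test asserts per simulation.

## Trait definitions

For branching number *b* within a replicate: BI = tips(b)/length(b),
BD = tips(b)/length(b−1), BR = tips(b)/axes(b−1); BD and BR are undefined at
b = 0 (`NA`, as trait tables print "n/a"). Because every simulated axis
carries exactly one tip, tip count equals axis count — the identity
BR = BD × mean parent length holds exactly and is tested. Zero denominators
raise a warning and return `NA` rather than a silent zero. Allocation
proportions between compartments, SRL (Σlength/Σbiomass) and biomass mass
fractions follow the standard definitions; fractions over compartments sum
to 1 by construction.

**Relative elongation rate.** Trace series record cumulative traced root
length per tracing day. Per interval, the absolute rate is ΔL/Δdays
(cm day⁻¹) and the relative rate divides by the traced length, ×10 for
mm cm⁻¹ day⁻¹. The source study's printed formula ("length increase divided
by the absolute rate, × 10") is dimensionally inconsistent with its stated
units — it reduces to 10·Δdays — so the package adopts the normalization
that reproduces the units; the literal printed form stays available behind
`literal = TRUE` for auditability. The normalizing length is the traced
total at the *end* of the interval (matching how traces accumulate; the
start-of-interval alternative is indistinguishable at the tracing density
used). Summaries use a 20% trimmed mean — `floor(0.2·n)` values dropped from
each tail, applied to the pooled per-treatment rate set — to guard against
the inflated ratios that short early-growth intervals produce.

## The synthetic experiment generator

`generate_experiment()` emulates the split-root study design: a
resource-partitioned treatment (9 replicates; distinct nutrient and water
calibrations) and a resource-mixed treatment (4 replicates; one calibration
on both sides). Per replicate and compartment it simulates a root system for
18 days, recording total length on a three-times-weekly tracing schedule
(days 2, 4, 7 of each week).

* **Trace observation model.** Only roots pressed against the observation
  window are traceable, so the traced length is the true total times a
  Beta(2, 8) visibility fraction (mean 0.2), drawn once per replicate and
  compartment and constant over time. This constant factor is the
  multiplicative observation noise; relative elongation rates are invariant
  to it, exactly as in the physical tracing protocol. Per-date jitter is
  deliberately absent: it would violate the monotonicity that cumulative
  traces must have.
* **Biomass noise.** Linear densities get a lognormal multiplier (CV 10%)
  per replicate and compartment, so SRL and mass fractions vary across
  clones the way per-plant table summaries do.

What the generator does *not* emulate: substrate heterogeneity and moisture
dynamics, root mortality and turnover, diameter plasticity (radii are fixed
per order), root hairs, hydraulic redistribution, and any chemistry
(nitrogen content, isotopic signatures). Passing tests therefore demonstrate
that the pipeline recovers its own generating parameters and the published
trait structure — not that the growth model is a validated description of
real root systems in substrate.

## Packaged calibrations

The study the package emulates did not publish its fitted growth parameters
in the main text, so the shipped `nutrient`, `water` and `mixed` calibrations
are **reverse-engineered stand-ins**, labelled as such. The procedure:

1. Closed-form initial values from the per-order trait tables: mean branch
   counts per parent from `(lmax − la − lb)/ln + 1`, mean parent length from
   BR/BD, per-order mean lengths from 1/BI, insertion angle means copied
   directly from the published branch angles.
2. Suppression of high branching numbers on the water side (the "sparse or
   absent orders ≥ 2" pattern) via three mechanisms consistent with the
   model's invariants: unbranched zones spanning the whole mean maximum
   length (so only above-average axes branch), branching intervals near or
   above `lmax`, and slow high-order elongation so late-emerging orders stay
   short by harvest.
3. Refinement on 30-replicate ensembles until branching density/ratio/angle,
   SRL, mass fractions, the allocation-by-order pattern and the trimmed-mean
   relative elongation rate sat within the replication tolerances; linear
   densities were then solved directly from simulated mean lengths so the
   compartment SRLs land on the published values with an even biomass split.

The harvest is day 18 and ensembles use 100 replicates (9 for the synthetic
experiment, matching the study's n) — sizes at which the full acceptance run
completes in about a minute on one CPU while ensemble standard errors stay
well inside the tolerances. Two published values are knowingly *not*
matched: the water-compartment branching density and the branching
intensities. The published table is internally inconsistent there — BR/BD
implies a mean primary length of ~7.8 cm in water versus ~9.0 cm in
nutrients, while the allocation results require water primaries to be
*longer* — so the water calibration honours BR (47.8) and the allocation
structure and lets BD fall where the identity puts it. A single simulator
cannot satisfy all three at once; this is a property of the published
summaries, not of the implementation.

## Statistics

Allocation is tested with exact two-sided binomial tests against an even
split, with continuous metrics discretized to 1-mm (length) or 1-mm²
(surface area) units — the discretization grain is our choice, needed to
cast continuous metrics as counts. Group comparisons use classical one-way
ANOVA (`F` on (k−1, N−k) df; all-identical input is defined as F = 0,
p = 1). The source study additionally fit negative-binomial mixed models for
count responses; random-effect machinery is out of scope here, and the
package's comparisons are deliberately the lightweight versions. The
binomial test's size under a symmetric null is verified against an exact
enumeration of the discrete null distribution.

## Numerical choices and edge cases

* Geometry resolution 0.1 cm; the final segment of an extension is partial
  so arc length is exact. Tolerances: 1e-9 for activation/length
  comparisons, 1e-6 relative for arc-length assertions, 6 decimal places
  (1e-6 cm) in RSML output.
* RSML documents carry no timestamps, so a seed reproduces output bytes;
  write → read → write is asserted byte-identical.
* `dt = 0` is an exact no-op; `n_replicates = 0` yields an empty result.
* With stochastic parameters, results are reproducible per seed *and* call
  schedule (growing in different step patterns consumes the RNG in a
  different order); the deterministic limit is schedule-invariant.
* The TOML reader covers the scalar/array subset the configuration schema
  uses; unknown keys warn (forward compatibility), invalid values error
  with the field name.

## Known limitations

Lengths and counts are exact under the growth law, but the law itself is the
simplest one consistent with the emulated study's description; elongation
that decelerates smoothly, emergence delays, or order-dependent tropism
would need the config switch left open for growth laws to be extended.
Biomass is strictly proportional to length per order. The barrier geometry
assumes the rhizome sits exactly over the gap. None of the statistics
correct for multiple testing, mirroring the emulated analysis.
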