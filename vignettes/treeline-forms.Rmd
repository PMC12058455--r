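---
title: "Quantifying treeline-ecotone forms: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying treeline-ecotone forms: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treelineform)
```

## The problem

Alpine treeline ecotones — the transition from closed upper-montane
forest to treeless alpine vegetation — take very different spatial
forms. Canopy height may fall gradually over a hundred metres or break
off within a single tree row; tree cover may end at a sharp, discrete
forest edge or thin out diffusely. These two axes, **abruptness**
(height decline) and **discreteness** (cover decline), carry
information about the demographic processes limiting trees at their
elevational limit, but they are hard to score consistently by eye.
`treelineform` computes scalar metrics for both axes from
individual-tree point patterns on a rectangular hillslope transect
(y = 0 at the bottom, elevation increasing uphill) and maps them to
categorical forms with explicit, adjustable thresholds.

## From points to belt vectors

The transect is divided into elevational belts (default 5 m) and each
belt into square subplots (default 5 × 5 m); a 180 × 60 m transect
yields 36 belts of 12 subplots. Subplot **canopy height** is the
height of the tallest individual strictly taller than the seedling
cutoff (default 0.5 m), or `NA` when there is none. Two belt vectors
are derived, bottom to top:

* `Max_H(y)` — the highest subplot canopy height in belt `y` (0 if the
  belt holds no individual above the cutoff). It deliberately retains
  isolated tall "outpost" trees, which demonstrate the growth
  potential of their belt.
* `Max2_H(y)` — the second-highest subplot canopy height (0 with fewer
  than two occupied subplots). With 12 subplots this is the belt-wise
  92nd percentile; it discounts single outposts.

Ties between subplots are read literally on the multiset of subplot
values: two subplots tied for the tallest canopy give
`Max2_H = Max_H`. Belt intervals are half-open `[low, high)` with the
top belt closed, so every in-bounds tree belongs to exactly one belt;
the boundary convention is a package choice, documented because trees
exactly on a boundary are assigned uphill.

## Abruptness

Height variation *inside* the forest must not register as abruptness.
Two transformations remove it:

1. **Truncation.** The truncation belt `y_t` is the topmost belt with
   `Max_H > 3` m (the forest cutoff; configurable). All belts at or
   below `y_t` are capped to `Max_H(y_t)`. We treat the condition
   above `y_t` as non-strict (`<= 3` m) so `y_t` is always defined
   when any belt exceeds the cutoff; requiring belts above `y_t` to be
   strictly below 3 m would leave a belt sitting exactly at 3 m with
   no valid truncation belt at all. If no belt exceeds the cutoff there is no
   forest on the transect and the metrics are reported as undefined
   rather than zero.
2. **Smoothing.** Descending from the topmost belt to `y_t + 1`, each
   value is replaced by its upslope neighbour when that neighbour is
   higher. Canopy gaps — which would otherwise mimic an abrupt
   decline at their downhill edge — are filled from above.

On the smoothed vector `sMax_H`, successive-belt differences
`delta(y) = sMax_H(y+1) - sMax_H(y)` are non-positive, and the four
metrics are the largest single-belt decline:

* `a_abr = -min(delta)` (m), from `Max_H`; `a_abr2` likewise from
  `Max2_H`.
* `n_abr = -min(delta / max(Max_H))`, normalised by the transect-wide
  maximum of the **raw** vector, so `n_abr` is the fraction of total
  forest stature lost in one belt step and lies in [0, 1]; `n_abr2`
  uses the raw `Max2_H` maximum.

`y_t` is found independently for `Max_H` and `Max2_H`; nothing forces
the second vector to reuse the first vector's truncation belt. Ties in
the minimising belt are reported at the lowest belt index; only the
reported location, never the metric value, depends on this. When the
smoothed vector is still positive at the topmost belt the decline lies
(at least partly) beyond the transect, and the result carries an
edge-truncation warning instead of a confident metric.

Absolute and normalised metrics answer different questions: `a_abr`
is comparable across sites in metres but scales with forest stature,
`n_abr` expresses the unrealised growth potential at the break. The
interpretation is resolution-dependent — `a_abr = 2` m on 5-m belts
means 0.4 m of height lost per metre, on 10-m belts only 0.2 m per
metre (`decline_per_meter()`).

A steep but continuous decline can straddle a belt boundary and be
split between two belts, deflating the metric. `belt_shift_scan()`
recomputes the pipeline at belt origins offset in 1-m steps (partial
belts at both ends retained): a genuine single-step decline is seen at
full size at every offset (low dispersion), a spread decline is not.

## Discreteness

Tree cover is rasterized by projecting circular crowns onto 1 × 1 m
cells and removing overlap: a cell's cover is the area fraction under
the **union** of crown disks, evaluated on a deterministic 10 × 10
subgrid of points per cell (`supersample`). The subgrid makes the
computation reproducible bit-for-bit and keeps the area error of a
metre-scale disk below about 1%; for the quadrature of a single
interior disk the total rasterized area is within 2% of the closed
form at the default resolution. Crowns are clipped at transect edges.
Records without a crown diameter get `crown_ratio × height` (default
½, a simplification used when allometric data are missing; 0.25 and
0.75 are worth testing as sensitivity bounds). All records with a
crown contribute to cover, including those below the seedling cutoff
— cover is physiognomic. Gridded cover from other sources (e.g.
classified imagery) can enter directly via `read_cover_grid()`.

Mean cover per subplot, placed at its belt midpoint, is fitted with a
three-parameter logistic along elevation:

C(y) = C_max / (1 + exp(s (y − y_l)))

with `C_max` the forest-interior cover, `y_l` the transition midpoint
and `s` the steepness — the discreteness metric. The fit is
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with `s`
constrained non-negative (cover must decline uphill). Starting values:
`C_max` from the mean cover of the two lowest belt positions, `y_l`
from the first crossing of half that value on a monotone envelope of
the cover profile (falling back to the transect midpoint), and `s`
from the set {0.1, 0.02, 0.05, 0.2, 0.5} taken as restarts, keeping
the lowest residual sum of squares. Data points are capped at 1 but
`C_max` is not: fits above 1 are legitimate descriptions of a plateau
the data only partly reach. One point per subplot (rather than one per
belt) implicitly weights belts by their subplot count.

A fit is only interpretable when both plateaus are inside the sampled
area. Status rules: `y_l` at or below 5 m (`y_l_margin_m`) or above
the transect length flag the midpoint as outside the interpretable
range; `C_max` below 0.4 (`c_max_min`) flags cover too low for a
discrete edge to exist; a steepness pinned at the zero bound or a
non-converged fit is a failure. When several rules would fire, the
midpoint rules take precedence over the cover rule — a midpoint
outside the transect invalidates `C_max` itself.

## Classification

Abruptness labels per metric (strict inequalities; between the cuts is
intermediate):

| metric | gradual below | abrupt above |
|---|---|---|
| `a_abr` | 2 m | 3 m |
| `a_abr2` | 1.5 m | 3 m |
| `n_abr`, `n_abr2` | 0.25 | 0.40 |

With a krummholz belt present, all absolute cuts drop by 1 m (the
reduction for `a_abr2`'s gradual cut is applied uniformly with the
rest); normalised cuts are unchanged. Krummholz presence is taken from
the records' `growth_form` flags or supplied explicitly — the package
does not detect krummholz from the pattern. The consensus is the
majority of defined per-metric labels, except that any
gradual-vs-abrupt disagreement yields `conflicting` (such sites need
manual assignment; the metrics are a continuous description first and
a key second). Ties resolve to intermediate.

Discreteness: status-ok fits with `s >= 0.2` are discrete, below it
diffuse. The boundary is included on the discrete side (conventions in the
literature differ on which side owns exactly 0.2; we use `>=` and
flag boundary hits in the report). `s >= 0.2` confines the fitted 80%-to-20% transition to
`2 ln(4)/s <= 13.9` m, about three 5-m belts. Low-forest-cover fits
are diffuse by definition; midpoint violations and failed fits are
unclassifiable. Heights flagged krummholz remain in the canopy-height
vectors (heights are heights); the flag only shifts thresholds.

## The synthetic generator

`generate_ecotone()` realises idealised ecotones with known ground
truth so that every metric can be tested without field data. Trees are
placed by an inhomogeneous Poisson process — field-calibrated
simulations of this system show no particular clustering, so no
interaction structure is imposed. The intensity is chosen so the
realised union-of-crowns cover tracks a logistic target profile
`C(y)`: for a Boolean model with disks of expected squared radius
`E[r²]`, coverage is `1 − exp(−λ π E[r²])`, hence
`λ(y) = −ln(1 − C(y)) / (π r(y)² (1 − ν + ν²/3))`, where
`r(y) = crown_ratio · H(y)/2` follows the height profile and the last
factor is the expected squared shrinkage from the multiplicative
height noise `(1 − ν U)`, `U ~ U(0,1)`. Realised bottom-belt cover
then matches the target to within sampling noise and edge-clipping
loss (about 1–2%).

Height profiles: `gradual_linear` declines from `h_max` to 0 at
`y_top`; `abrupt_step` holds `h_max` below `y_step` and a residual
height above it. The residual (default 0.3 m) must stay below the
seedling cutoff so that the step in the canopy-height vectors is
exactly `h_max`. Where the target cover is unreachable with the local
crown size — sub-seedling vegetation above a step — the intensity
saturates at 2 trees/m² (a dense seedling carpet) instead of
diverging; if saturation would occur at forest stature the scenario is
rejected as unrealisable. Default noise ν = 0.1 gives a realistic
within-stand height scatter of up to 10%. An optional krummholz belt
caps heights over a y-range and flags those records.

What the generator does *not* emulate: clustering and island
formation, growth/mortality dynamics, non-circular crowns, terrain
anisotropy, and sinuous (non-straight) treelines. Passing recovery
tests therefore show that the metrics recover the parameters of
clean, straight, Poisson ecotones — not that they are robust to every
field complication; the discreteness of strongly sinuous treelines in
particular will be underestimated by any straight-belt method.

## Numerical choices and problem sizes

* Supersampling is a fixed subgrid, not Monte Carlo: rasterization is
  deterministic, so a rerun of the pipeline on the same input yields a
  byte-identical report.
* The generator restores the caller's RNG state; patterns are a pure
  function of (scenario, seed).
* Recovery studies in the test-suite and the acceptance script use
  the 180 × 60 m reference transect: steepness recovery over
  `s_true ∈ {0.05, 0.1, 0.2, 0.4} × C_max ∈ {0.4, 0.6, 0.8}` with 20
  seeds per cell (240 runs), abruptness recovery over step heights
  {4, 6, 8} m with 20 seeds each. The ensemble median of the relative
  steepness error is about 11–14%; the least-informed cell
  (C_max = 0.4 with a steep transition) is noisier than the rest
  because a 40% cover plateau leaves few cover units to distinguish
  transition shapes, and because fitted `C_max` then straddles the
  0.4 validity cut.
* Steep transitions are recovered with a mild downward bias: belt
  binning (cover evaluated at belt midpoints) and the crown footprint
  itself both smear a sharp cover step over 1–3 m.

## Worked example

```{r example}
spec <- transect_spec(length = 180, width = 60)
scenario <- ecotone_scenario(spec = spec, form_height = "abrupt_step",
                             h_max = 8, y_step = 100,
                             c_max = 0.8, y_l = 100, s = 0.4, seed = 7)
sim <- generate_ecotone(scenario)
report <- treeline_metrics(sim$trees, spec)
report$abruptness$a_abr          # close to the 8-m step
report$abruptness_class$consensus
report$discreteness$s            # well above the 0.2 cut
report$discreteness_class$label
```

## Limitations

* The thresholds are conventions with a narrow calibration base; they
  are defaults in `classification_thresholds()`, not constants.
* Metrics are belt-resolution statements; wider belts make the same
  physical decline look more gradual, and a decline split across a
  belt boundary is deflated (use `belt_shift_scan()` to detect this).
* A transect must contain forest above the cutoff, a cover plateau at
  the bottom, and bare ground at the top for all metrics to be
  interpretable; the status and warning machinery reports, rather than
  hides, violations.
* Crown geometry is circular and cover is purely horizontal; no
  allometric uncertainty is propagated.
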