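---
title: "Quantifying vertical vegetation belts with the normal cloud model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vertical vegetation belts with the normal cloud model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertibelt)
```

## The problem

On a forested mountain, vegetation types replace one another with
elevation, but the belts have no sharp edges. Each belt has a **core
zone** — the interval of permanent establishment — flanked by an **upper
and a lower extension zone** where its stands interdigitate with the
neighbouring belts. Inside those transition zones, which patch belongs to
which belt is partly random, and where one belt "ends" is fuzzy. Classical
belt maps with hard boundaries discard exactly this information.

`vertibelt` treats the *distribution height* of a belt (or of one of its
zones) as a qualitative concept realised by a population of sampled
elevations, and summarises it with the three numerical features of the
normal cloud model:

* **Ex** (expectation, m) — the central elevation of the concept;
* **En** (entropy, m) — the width/fuzziness of the distribution height;
* **He** (hyper-entropy, m) — the dispersion of En itself, i.e. how
  variable the fuzziness is (the randomness of the patches).

## The estimators

Given sampled elevations $x_1,\dots,x_n$, the backward (reverse) cloud
generator in `backward_cloud()` computes

$$Ex = \bar{x}, \qquad
  En = \sqrt{\tfrac{\pi}{2}}\cdot\frac{1}{n}\sum_i |x_i - Ex|, \qquad
  He = \sqrt{S - En^2},$$

with $S$ the sample variance using divisor $n-1$. Two numerical details
are deliberate:

* $S$ is computed with divisor $n - 1$ exactly as the estimator family is
  conventionally written, even though it is simply called "variance";
* for platykurtic samples the radicand $S - En^2$ can be negative. We
  clamp $He$ to 0 and set a `degenerate` flag instead of erroring, so a
  pipeline keeps running on odd strata while the flag survives into every
  report. `backward_cloud(c(-1, -1, 1, 1))` is the canonical example.

The mean-absolute-deviation form of $En$ makes it a consistent estimator
of $\sigma$ for Gaussian data, because
$\sqrt{\pi/2}\;\mathbb{E}|x-\mu| = \sigma$: the test suite checks
$|\widehat{En}-\sigma|/\sigma < 2\%$ at $n = 10^5$.

The forward generator `forward_cloud()` inverts the model: for each of
$m$ droplets it draws $En' \sim \mathcal{N}(En, He)$, then
$x \sim \mathcal{N}(Ex, En')$, and attaches the membership degree

$$C_T(x) = \exp\!\left(-\frac{(x - Ex)^2}{2\,En'^2}\right).$$

Numerical choices where the estimator family is silent:

* $En' \le 0$ can occur whenever $He > 0$; such draws are
  rejection-resampled until positive, under the call's own seed, so the
  droplet sequence is fully reproducible.
* $En = 0$ (all samples identical) short-circuits to $m$ copies of
  $(Ex, 1)$; `membership()` itself still refuses $En' \le 0$.
* Every stratum needs at least `min_points = 3` samples — with fewer, the
  three moments are meaningless — and undersized strata are *reported as
  skipped*, never silently dropped.
* The default droplet count is 2,000, enough for a dense cloud map while
  keeping output files small; it is a config key, not a constant.

## Delineating the internal structure of a belt

The zonation follows the area-proportion gradient, not expert judgement:

1. `bin_proportions()` computes, for 50 m elevation bins (left-closed,
   right-open, origin snapped to a multiple of the width), the percentage
   of bin area occupied by each forest type. Area is cell count times
   cell area.
2. `main_range()` finds the elevation interval where the type mainly
   occurs: the longest contiguous run of bins at or above a floor
   percentage (default 10%). Ties go to the run holding the higher peak,
   then to the lower run. Because published analyses typically choose
   this range by inspecting the profile, an explicit interval override is
   also accepted — that is the faithful mode when reproducing a reported
   range.
3. `zone_threshold()` takes the *unweighted arithmetic mean* of the
   per-bin percentages over the main range. A fixed threshold can be
   substituted for types whose concentrated distribution is too narrow
   for the mean rule (30% is the conventional fallback).
4. `delineate_zones()` marks as **core** the contiguous run of bins whose
   percentage *strictly exceeds* the threshold and which contains the
   peak bin ("greater than" is read literally: bins exactly at the
   threshold fall to the extensions). Everything below the core is the
   lower extension, everything above the upper extension, both
   open-ended and clipped to the DEM range only at reporting time.
   Isolated super-threshold bins outside the chosen run are warned
   about, not merged — a belt is reported as a single interval.

These rules make the zone partition total: every elevation belongs to
exactly one of {core, upper, lower} for each type, which the sampling
module relies on.

## Sampling and terrain stratification

`sample_points()` lays a regular grid (default 200 m spacing) inset half
a spacing from the lower-left corner of the extent, extracts the
containing-cell elevation, computes aspect with Horn's 8-neighbour
finite differences (border cells by edge replication; gradient magnitude
below `1e-8` counts as flat), and classifies aspect into **sunny**
([112.5°, 292.5°), the south-facing half) and **shady** (everything
else, including flat). Elevation classes default to interior edges at
550 / 900 / 1100 / 1350 m; all intervals are left-closed right-open.
Points on nonforest stands are retained in the table but excluded from
cloud fitting.

## Forest typing

Stand composition uses the forestry tenths convention: each species'
share in tenths, summing to 10, written as e.g. `"7QUE3PIN"`. A stand is
pure deciduous broadleaf (or pure conifer) when its broadleaf (conifer)
tenths reach **7**; everything between is mixed. The inventory phrase
"exceeded 7 (up to 10)" is ambiguous about exactly 7; we read it
inclusively ($\ge 7$), matching standard composition rules, and expose
the cut as `pure_threshold_tenths` so the strict reading is one argument
away. Stands containing an unresolvable species code fail loudly rather
than being dropped.

## What the synthetic mountain emulates — and what it does not

Real stand inventories of this kind are rarely redistributable, so the
package ships a generator with analytic ground truth.

* **Terrain**: a radially symmetric cone (base 150 m, summit 1445 m on a
  5 km × 5 km, 25 m grid by default) plus Gaussian-smoothed white noise
  rescaled to `roughness` and clamped at 3σ. The cone keeps sunny and
  shady cells balanced. The summit is deliberately *off* the 50 m bin
  lattice: a peak cell sitting exactly on a bin edge forms a degenerate
  one-cell bin whose 100% proportion would distort the mean threshold.
* **Belts**: per type, occupancy weight 1 on a plateau
  `center ± core_halfwidth` with exponential tails
  (`lower_decay = 70 m` below, `upper_decay = 40 m` above — the lower
  transition wider, echoing the classical internal-structure theory). A
  constant background weight turns `nonforest_frac` (default 0.35) into
  the nonforest share where one belt is at full strength, and makes the
  mountain base tend to pure nonforest. Weights are normalised to
  probabilities per cell.
* **Topmost belt**: its upper decay is inert — there is no higher belt
  to hand over to, so its occupancy saturates upward. With a constant
  background weight this is also the only configuration under which
  top-belt occupancy is monotone above its lower core edge, a property
  the test suite asserts.
* **Recoverability as a design constraint**: the decay scales and
  background weight were chosen, once, from the closed-form curves so
  that the mean-threshold rule recovers each plateau within one 50 m bin
  on noise-free data; every decision bin sits several percentage points
  clear of the threshold. This couples the generator to the delineation
  rule by design — the point of the truth record is that the pipeline
  can be validated against it.
* **Aspect response**: sunny cells shift each belt centre by
  `aspect_shift` (defaults +30 m for broadleaf, −30 m for conifer:
  broadleaves reach higher on sunny slopes, conifers on shady ones).
* **Patches**: labels are drawn on a coarse grid of `patch_scale` cells
  (default 2) and upsampled, mimicking polygonal stands rather than
  per-pixel noise. `mode = "modal"` replaces all draws by their modes
  for noise-free checks.

The generator does **not** emulate: multi-peak or hydrologically
realistic terrain, real taxonomies or species distribution models,
temporal succession, management history, or spatially correlated
composition *within* a type. Passing the recovery and fidelity tests
therefore shows the pipeline is correct under a belt-structured world
with patch noise — it says nothing about classification error or
inventory bias in real data.

## Reference values and worked examples

`taishan_unit_clouds()` ships the published per-unit (elevation class ×
aspect × type) Ex/En/He values for Mount Taishan's belts as plain text.
They are used as *input* to `ex_differences()`: in the elevation classes
below 550 m and between 900 and 1100 m, the deciduous-vs-mixed
expectation gaps span 22.82–39.15 m while conifer-vs-mixed gaps span
only 4.79–7.94 m — the pattern read as deciduous broadleaf species
encroaching on conifer habitat at low elevation. The package recomputes
these from the table at run time; it does not (and cannot) refit the
underlying clouds, since the source DEM and inventory are not public.

## Problem sizes used by the tests

Chosen as the package's own validation design: core recovery runs on a
301 × 301 noise-free landscape (≈ 90k cells, ≥ 400 cells in every
decision bin); generator fidelity on the default 200 × 200 stochastic
landscape (tolerance ±5 percentage points in bins with ≥ 400 cells);
estimator identities at $n = m = 10^5$; and the end-to-end pipeline on a
500 × 500-cell mountain sampled at 200 m (3,844 points), run twice to
assert byte-identical outputs under a fixed seed.

## Known limitations

* The mean-threshold rule assumes a unimodal proportion profile per
  type; genuinely bimodal belts trigger the isolated-bin warning but are
  still reported as a single core interval.
* He is a second-order moment difference and is noisy: round-trip
  recovery is only asserted within ±50% even at $10^5$ droplets.
* Areas are cell counts; no polygon geometry is supported, so
  sub-cell stand boundaries are quantised to the raster.
* Aspect at border cells uses replicated-edge differences; on sharply
  curved borders the angle is approximate (interior cells are exact for
  planar slopes).
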